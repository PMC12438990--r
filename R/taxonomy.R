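#' @importFrom rlang .data
#' @importFrom lubridate %m+% months ymd year
#' @importFrom stats aov pnorm qnorm rbinom rexp rnorm runif sd setNames t.test
#' @importFrom utils head
NULL

# Sentinel states that sequences may contain but ICD-10 mapping never produces.
ABSORBING_STATES <- c("DEAD", "EMIGRATED")

#' Validate and normalize ICD-10 mental-disorder codes
#'
#' Codes are expected at the two-cipher level with an optional subcode, i.e.
#' `"F"` followed by two digits and optionally a dot and one or two further
#' digits (`"F84"`, `"F84.0"`, `"F32.11"`). Normalization strips whitespace
#' and upper-cases.
#'
#' @param code Character vector of raw codes.
#' @return Normalized character vector.
#' @examples
#' icd10_normalize(c(" f84.0", "F32"))
#' @export
icd10_normalize <- function(code) {
  toupper(gsub("[[:space:]]+", "", as.character(code)))
}

#' @rdname icd10_normalize
#' @details `icd10_validate()` throws an error naming the first offending
#'   token if any normalized code does not match the expected pattern.
#' @return `icd10_validate()` returns the normalized codes invisibly.
#' @export
icd10_validate <- function(code) {
  x <- icd10_normalize(code)
  bad <- x[!grepl("^F[0-9]{2}(\\.[0-9]{1,2})?$", x)]
  if (length(bad) > 0) {
    stop("malformed ICD-10 code: '", bad[[1]], "'", call. = FALSE)
  }
  invisible(x)
}

is_valid_icd10 <- function(code) {
  grepl("^F[0-9]{2}(\\.[0-9]{1,2})?$", icd10_normalize(code))
}

#' Load a diagnostic-category taxonomy
#'
#' Reads a rule file mapping ICD-10 code prefixes to diagnostic categories.
#' Each row gives a category label, a `;`-separated list of included code
#' prefixes and an optional `;`-separated list of excluded subcode prefixes.
#' Matching is by longest prefix, so a subcode rule such as `F84.2` takes
#' precedence over its parent block `F84`. The default file encodes the
#' 19-category grouping used throughout the package (substance use through
#' "other"); codes claimed by no rule map to `"UNMAPPED"`.
#'
#' @param path Path to the taxonomy file. Defaults to the shipped file.
#' @return An object of class `diag_taxonomy`: a list with `rules` (tibble of
#'   `prefix`, `category`), `categories` (character vector of mappable
#'   labels) and `source` (the file path).
#' @export
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diagnostic_categories.csv",
                        package = "diagtraj", mustWork = TRUE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  need <- c("category", "include", "exclude")
  if (!all(need %in% names(raw))) {
    stop("taxonomy file must have columns: ", paste(need, collapse = ", "))
  }
  split_list <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || s == "") character(0) else icd10_normalize(strsplit(s, ";")[[1]])
    })
  }
  inc <- split_list(raw$include)
  exc <- split_list(raw$exclude)
  rules <- tibble::tibble(
    prefix = unlist(inc),
    category = rep(raw$category, lengths(inc))
  )
  # An excluded subcode maps to whatever other category claims it; if none
  # does, it maps to UNMAPPED via an explicit rule so the longest-prefix
  # match cannot fall back to the parent block.
  orphan <- setdiff(unlist(exc), rules$prefix)
  if (length(orphan) > 0) {
    rules <- dplyr::bind_rows(
      rules, tibble::tibble(prefix = orphan, category = "UNMAPPED")
    )
  }
  dup <- rules$prefix[duplicated(rules$prefix)]
  if (length(dup) > 0) {
    stop("taxonomy rules overlap: prefix '", dup[[1]],
         "' claimed more than once")
  }
  structure(
    list(
      rules = rules,
      categories = sort(unique(rules$category[rules$category != "UNMAPPED"])),
      source = path
    ),
    class = "diag_taxonomy"
  )
}

#' @export
print.diag_taxonomy <- function(x, ...) {
  cat("<diag_taxonomy> ", length(x$categories), " categories, ",
      nrow(x$rules), " prefix rules\n", sep = "")
  cat("  categories:", paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Map ICD-10 codes to diagnostic categories
#'
#' Applies longest-prefix matching against the taxonomy rules. Subcode-level
#' exclusions (e.g. `F84.2` belonging to `OTHER` rather than `ASD`) win over
#' block-level inclusion. Codes covered by no rule (for instance the organic
#' block F00-F09) return `"UNMAPPED"`.
#'
#' @param code Character vector of ICD-10 codes.
#' @param taxonomy A `diag_taxonomy`, as from [load_taxonomy()].
#' @return Character vector of category labels (`"UNMAPPED"` where no rule
#'   applies).
#' @examples
#' tax <- load_taxonomy()
#' map_code_to_category(c("F84.0", "F84.3", "F98.8", "F93.1"), tax)
#' @export
map_code_to_category <- function(code, taxonomy) {
  stopifnot(inherits(taxonomy, "diag_taxonomy"))
  x <- icd10_validate(code)
  rules <- taxonomy$rules
  vapply(x, function(cd) {
    hit <- startsWith(cd, rules$prefix)
    if (!any(hit)) return("UNMAPPED")
    m <- rules[hit, ]
    m$category[[which.max(nchar(m$prefix))]]
  }, character(1), USE.NAMES = FALSE)
}

#' Map ICD-10 codes to one-cipher chapters
#'
#' Truncates to the first cipher: `"F32.1"` belongs to chapter `"F3"`. This is
#' the resolution at which subsequent-diagnosis outcomes are defined for the
#' hazard contrasts.
#'
#' @inheritParams map_code_to_category
#' @return Character vector of chapter labels `"F0"` .. `"F9"`.
#' @export
map_code_to_chapter <- function(code) {
  x <- icd10_validate(code)
  substr(x, 1, 2)
}

#' Number of mappable categories in a taxonomy
#'
#' @inheritParams map_code_to_category
#' @return Integer count of distinct categories reachable from ICD-10 codes
#'   (absorbing states excluded).
#' @export
category_count <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "diag_taxonomy"))
  length(taxonomy$categories)
}

#' The full sequence alphabet
#'
#' @inheritParams map_code_to_category
#' @return Character vector: the taxonomy's categories in a fixed clinical
#'   ordering followed by the absorbing states `DEAD` and `EMIGRATED`.
#' @export
state_alphabet <- function(taxonomy) {
  canonical <- c("SUD", "SZ", "BD", "SRD", "OMD", "AND", "OCD", "SAD", "SOM",
                 "ED", "PD", "ID", "ODD", "ASD", "ADHD", "CD", "AD", "TD",
                 "OTHER")
  cats <- c(intersect(canonical, taxonomy$categories),
            setdiff(taxonomy$categories, canonical))
  c(cats, ABSORBING_STATES)
}

#' Enumerate the concrete codes a category's rules admit
#'
#' Used by the cohort simulator to draw a concrete ICD-10 code for a sampled
#' category. Returns the category's include prefixes themselves, each of which
#' maps back to the category under longest-prefix matching.
#'
#' @inheritParams map_code_to_category
#' @return Named list of character vectors, one per category.
#' @export
category_code_pools <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "diag_taxonomy"))
  rules <- taxonomy$rules[taxonomy$rules$category != "UNMAPPED", ]
  split(rules$prefix, rules$category)
}
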