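#' Run the full trajectory-analysis pipeline
#'
#' Executes the stages end to end — optional simulation, ingest, sequence
#' building, entropy, shifts, hazard contrasts, plots — writing tabular
#' outputs, plot images with metadata sidecars, and a run manifest (package
#' version, seed, config hash, row counts per stage) to `out_dir`. Any
#' stage failure aborts with an error naming the stage; outputs of earlier
#' stages are retained.
#'
#' @param config A named list, or path to a YAML/JSON file, with elements:
#'   `simulate` (a list of [cohort_config()] arguments) *or* `records` (path
#'   to an event file); optional `analysis` (`alphabet_size`, `min_count`,
#'   `by`), `cox` (`enabled`, `horizon_days`), `plots` (`enabled`,
#'   `max_strata`).
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$simulate$seed` when given.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "diagtraj",
    version = as.character(utils::packageVersion("diagtraj")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = list()
  )
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  taxonomy <- stage("taxonomy", function() {
    if (!is.null(config$taxonomy)) load_taxonomy(config$taxonomy)
    else load_taxonomy()
  })

  ingest <- stage("ingest", function() {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      if (!is.null(seed)) args$seed <- seed
      cc <- do.call(cohort_config, args)
      sim <- generate_cohort(cc, taxonomy)
      write_records(sim$records, file.path(out_dir, "records.csv"))
      list(records = sim$records, seed = cc$seed)
    } else if (!is.null(config$records)) {
      got <- read_records(config$records)
      write_ingest_report(got$report, file.path(out_dir, "ingest_report.json"))
      list(records = got$records,
           report = list(n_total = got$report$n_total,
                         n_rejected = got$report$n_rejected))
    } else {
      stop("config needs either 'simulate' or 'records'")
    }
  })
  records <- ingest$records
  manifest$seed <- ingest$seed
  manifest$ingest <- ingest$report
  manifest$stages$ingest <- nrow(records)

  analysis <- config$analysis
  alphabet_size <- analysis$alphabet_size %||% 21
  min_count <- analysis$min_count %||% 5
  by <- analysis$by %||% c("d1_category", "sex")

  seqs <- stage("sequences", function() {
    s <- build_sequences(records, taxonomy)
    out <- as.data.frame(s)
    out$d1_date <- format(out$d1_date, "%Y-%m-%d")
    readr::write_csv(out, file.path(out_dir, "sequences.csv"))
    s
  })
  manifest$stages$sequences <- nrow(seqs)

  summ <- stage("entropy", function() {
    ent <- sequence_entropy(seqs, alphabet_size)
    readr::write_csv(ent, file.path(out_dir, "entropy.csv"))
    sm <- summarize_entropy(seqs, by = by, alphabet_size = alphabet_size,
                            min_n = min_count)
    readr::write_csv(format_entropy_summary(sm),
                     file.path(out_dir, "entropy_summary.csv"))
    sm
  })
  manifest$stages$entropy <- nrow(summ)

  manifest$stages$shifts <- stage("shifts", function() {
    sh <- shift_summary(seqs, by = by)
    readr::write_csv(sh, file.path(out_dir, "shift_summary.csv"))
    readr::write_csv(shift_summary(seqs, by = "sex"),
                     file.path(out_dir, "shift_by_sex.csv"))
    nrow(sh)
  })

  if (isTRUE(config$cox$enabled %||% TRUE)) {
    manifest$stages$cox <- stage("cox", function() {
      grid <- hazard_contrast_grid(
        records, taxonomy,
        horizon_days = config$cox$horizon_days %||% 3652)
      readr::write_csv(grid$contrasts, file.path(out_dir, "cox_contrasts.csv"))
      jsonlite::write_json(grid$plan, file.path(out_dir, "cox_plan.json"),
                           auto_unbox = TRUE, digits = NA)
      nrow(grid$contrasts)
    })
  }

  if (isTRUE(config$plots$enabled %||% TRUE)) {
    manifest$stages$plots <- stage("plots", function() {
      plot_dir <- file.path(out_dir, "plots")
      dir.create(plot_dir, showWarnings = FALSE)
      sets <- build_sequence_set(seqs, by = c("d1_category", "sex"))
      sizes <- vapply(sets, nrow, integer(1))
      pick <- head(names(sort(sizes, decreasing = TRUE)),
                   config$plots$max_strata %||% 4)
      for (nm in pick) {
        freq <- sequence_frequency_table(sets[[nm]], min_count = min_count)
        sp <- plot_sequence_frequency(freq, title = nm)
        save_seq_plot(sp, file.path(
          plot_dir, paste0("seqfreq_", gsub("/", "_", nm), ".png")))
      }
      save_seq_plot(plot_entropy_bars(summ, title = "Mean normalized entropy"),
                    file.path(plot_dir, "entropy_bars.png"))
      length(pick) + 1L
    })
  }

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
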