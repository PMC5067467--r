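#' Write battery results to disk
#'
#' Emits the training table (10 bin columns per condition plus the repeated
#' ANOVA), the test table (ND and D blocks with per-lever means and t/p),
#' the devaluation verdicts, the per-replicate press counts, and a run
#' manifest. File contents are deterministic given identical inputs.
#'
#' @param battery An `ide_battery` from [run_battery()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(battery, outdir) {
  stopifnot(inherits(battery, "ide_battery"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(battery)
  files <- c(training = file.path(outdir, "training_bins.csv"),
             test = file.path(outdir, "test_counts.csv"),
             verdicts = file.path(outdir, "ide_verdicts.csv"),
             replicates = file.path(outdir, "replicate_counts.csv"),
             manifest = file.path(outdir, "manifest.json"))
  utils::write.csv(s$training, files["training"], row.names = FALSE)
  utils::write.csv(s$test[setdiff(names(s$test), "ide")], files["test"],
                   row.names = FALSE)
  utils::write.csv(s$test[c("condition", "nd_p", "d_p", "ide")],
                   files["verdicts"], row.names = FALSE)
  reps <- do.call(rbind, lapply(names(battery$conditions), function(nm) {
    cc <- battery$conditions[[nm]]
    data.frame(condition = nm, replicate = seq_len(nrow(cc$nd)),
               nd_a1 = cc$nd[, 1], nd_a2 = cc$nd[, 2],
               d_a1 = cc$d[, 1], d_a2 = cc$d[, 2])
  }))
  utils::write.csv(reps, files["replicates"], row.names = FALSE)
  ex <- battery$config$experiment
  manifest <- list(
    package = "devalsim",
    version = as.character(utils::packageVersion("devalsim")),
    conditions = names(battery$conditions),
    n_reps = ex$n_reps, base_seed = ex$base_seed, variant = ex$variant,
    config_hash = config_hash(battery$config))
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(files)
}

# stable digest of the configuration (order-independent within sections)
config_hash <- function(config) {
  attr(config, "defaulted") <- NULL
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x", h)
}

#' Render battery figures
#'
#' Writes one grouped bar-chart panel per condition (mean presses per
#' action, ND vs D extinction tests) and one learning-curve figure, as PNG.
#' An empty battery produces no files.
#'
#' @param battery An `ide_battery`.
#' @param outdir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
render_figures <- function(battery, outdir) {
  stopifnot(inherits(battery, "ide_battery"))
  if (!length(battery$conditions)) return(invisible(character(0)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(outdir, "test_counts.png")
  grDevices::png(f1, width = 1200, height = 800, res = 120)
  plot(battery, which = "test")
  grDevices::dev.off()
  f2 <- file.path(outdir, "learning_curves.png")
  grDevices::png(f2, width = 900, height = 700, res = 120)
  plot(battery, which = "training")
  grDevices::dev.off()
  invisible(c(f1, f2))
}
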