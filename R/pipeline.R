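# Orchestration of the two end-to-end workflows: profiling (peptide table ->
# register alignment -> matrices -> consensus -> primary-specificity call)
# and scanning (specificity model + FASTA -> candidate cleavage sites). Each
# run writes its artifacts plus a log with the resolved configuration, all
# seeds and artifact checksums; identical inputs give identical checksums.

run_log <- function(path, config, files) {
  lines <- c("# run log",
             vapply(names(config), function(k) {
               paste0(k, ": ", paste(format(config[[k]]), collapse = " "))
             }, character(1)),
             "checksums:",
             vapply(files, function(f) {
               paste0("  ", basename(f), ": ", unname(tools::md5sum(f)))
             }, character(1)))
  writeLines(lines, path)
  path
}

#' Profile cleavage specificity from a sequenced peptide table
#'
#' Chains [read_peptide_table()], [align_registers()], [build_pfm()],
#' [pfm_to_pwm()], [derive_consensus()] and
#' [classify_specificity_from_pwm()], writing the matrix file, the consensus
#' grammar string, the per-peptide alignment table and a run log under
#' `out_dir`.
#'
#' @param peptide_table Path to a peptide table, or a peptide data.frame.
#' @param out_dir Output directory (created if missing).
#' @param dialect Peptide-table dialect.
#' @param context A [library_context()].
#' @param window_positions Alignment window subsites.
#' @param pseudocount,background,seed,n_starts See [align_registers()].
#' @param run_id Identifier used in artifact names.
#' @return List of class `"run_report"`: per-stage summaries, the fitted
#'   objects (`aligned`, `pfm`, `pwm`, `pattern`, `call`) and artifact
#'   paths; all paths exist at return time.
#' @export
run_profile <- function(peptide_table, out_dir, dialect = "plain",
                        context = library_context(),
                        window_positions = subsite_window(),
                        pseudocount = 0.5, background = NULL, seed = 1L,
                        n_starts = 10L, run_id = "profile") {
  input_name <- if (is.character(peptide_table)) peptide_table else
    "<in-memory peptide table>"
  peptides <- if (is.data.frame(peptide_table)) peptide_table else
    read_peptide_table(peptide_table, dialect = dialect)
  if (nrow(peptides) == 0) {
    stop("profile: no peptides in input ", input_name)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aligned <- align_registers(peptides, context = context,
                             window_positions = window_positions,
                             pseudocount = pseudocount,
                             background = background, seed = seed,
                             n_starts = n_starts)
  pfm <- build_pfm(aligned, pseudocount = pseudocount)
  bg <- if (is.null(background)) rep(1 / 20, 20) else background
  pwm <- pfm_to_pwm(pfm, bg)
  pattern <- derive_consensus(pfm)
  call <- classify_specificity_from_pwm(pwm)

  matrix_path <- file.path(out_dir, paste0(run_id, "_matrix.txt"))
  write_matrix(pfm, matrix_path, background = bg)
  consensus_path <- file.path(out_dir, paste0(run_id, "_consensus.txt"))
  writeLines(format_pattern(pattern), consensus_path)
  alignment_path <- file.path(out_dir, paste0(run_id, "_alignment.tsv"))
  write.table(aligned$assignments, alignment_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  config <- list(run_id = run_id, input = input_name,
                 n_peptides = nrow(peptides),
                 window = paste(window_positions, collapse = " "),
                 pseudocount = pseudocount, seed = seed,
                 n_starts = n_starts, iterations = aligned$iterations,
                 objective = sprintf("%.6f", aligned$objective),
                 specificity = call$label)
  log_path <- file.path(out_dir, paste0(run_id, "_run.log"))
  run_log(log_path, config, c(matrix_path, consensus_path, alignment_path))
  structure(list(run_id = run_id, config = config, aligned = aligned,
                 pfm = pfm, pwm = pwm, pattern = pattern, call = call,
                 paths = list(matrix = matrix_path,
                              consensus = consensus_path,
                              alignment = alignment_path, log = log_path)),
            class = "run_report")
}

#' Scan a protein collection with a specificity model
#'
#' Chains [read_fasta()], [scan_proteins()] and [write_hits()]; the report
#' carries per-protein hit counts and the scan log (skipped windows are
#' never silently dropped).
#'
#' @param model A `"subsite_pwm"`, `"consensus_pattern"`, a pattern grammar
#'   string, or the path to a matrix file.
#' @param fasta Path to a FASTA file or a protein data.frame.
#' @param out_dir Output directory.
#' @param options A [scan_options()].
#' @param background Background for a matrix-file model.
#' @param run_id Identifier used in artifact names.
#' @return List of class `"run_report"` with `hits`, `hit_counts` per
#'   protein, the scan log and artifact paths.
#' @export
run_scan <- function(model, fasta, out_dir, options = scan_options(),
                     background = NULL, run_id = "scan") {
  if (is.character(model) && length(model) == 1) {
    model <- if (file.exists(model)) {
      pfm <- read_matrix(model)
      bg <- if (!is.null(background)) background else attr(pfm, "background")
      pfm_to_pwm(pfm, bg)
    } else {
      parse_pattern(model)
    }
  }
  proteins <- if (is.data.frame(fasta)) fasta else read_fasta(fasta)
  if (nrow(proteins) == 0) stop("scan: no proteins in input")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hits <- scan_proteins(proteins, model, options)
  hits_path <- file.path(out_dir, paste0(run_id, "_hits.tsv"))
  write_hits(hits, hits_path)
  counts <- table(factor(hits$protein_id, levels = proteins$id))
  config <- list(run_id = run_id,
                 mode = if (inherits(model, "subsite_pwm")) "pwm" else "pattern",
                 n_proteins = nrow(proteins), n_hits = nrow(hits),
                 report_span = paste(options$report_span, collapse = ".."),
                 threshold = options$threshold,
                 n_evaluated = attr(hits, "log")$n_evaluated,
                 n_skipped = attr(hits, "log")$n_skipped)
  log_path <- file.path(out_dir, paste0(run_id, "_run.log"))
  run_log(log_path, config, hits_path)
  structure(list(run_id = run_id, config = config, hits = hits,
                 hit_counts = counts, scan_log = attr(hits, "log"),
                 paths = list(hits = hits_path, log = log_path)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report:", x$run_id, "\n")
  for (k in names(x$config)) {
    cat(sprintf("  %s: %s\n", k, paste(format(x$config[[k]]), collapse = " ")))
  }
  invisible(x)
}
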