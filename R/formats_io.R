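# Readers and writers for the package's external representations: peptide
# tables from phage-display sequencing, FASTA protein collections, specificity
# matrix files and scan-hit reports. All coordinates in reports are 1-based
# inclusive.

read_source_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (is.character(source) && length(source) == 1 &&
      !grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  # literal text: one string with embedded newlines, or a vector of lines
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

#' Read a peptide table from phage-display sequencing
#'
#' One sequenced phage clone per non-comment line. In the `"plain"` dialect a
#' line is a bare 9-residue insert; in the `"delimited"` dialect it is
#' `sequence[,count[,label]]` (comma or tab separated). Duplicate sequences are
#' preserved as separate rows; collapsing is a downstream choice.
#'
#' @param source File path, connection, or literal text.
#' @param dialect `"plain"` or `"delimited"`.
#' @param insert_length Required insert length (9 for the nonamer library).
#' @return A data.frame with columns `sequence`, `count`, `label`.
#' @export
read_peptide_table <- function(source, dialect = c("plain", "delimited"),
                               insert_length = 9L) {
  dialect <- match.arg(dialect)
  lines <- read_source_lines(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) {
    return(data.frame(sequence = character(), count = integer(),
                      label = character()))
  }
  seqs <- character(length(rows))
  counts <- integer(length(rows))
  labels <- character(length(rows))
  for (i in seq_along(rows)) {
    ln <- trimws(lines[rows[i]])
    if (dialect == "plain") {
      fields <- ln
    } else {
      fields <- trimws(strsplit(ln, "[,\t]")[[1]])
    }
    seq <- toupper(fields[1])
    if (nchar(seq) != insert_length) {
      stop(sprintf("row %d: expected a %d-residue sequence, got %d ('%s')",
                   rows[i], insert_length, nchar(seq), seq))
    }
    if (!is_valid_aa(seq)) {
      stop(sprintf("row %d: non-amino-acid character in '%s'", rows[i], seq))
    }
    cnt <- 1L
    if (length(fields) >= 2 && nzchar(fields[2])) {
      cnt <- suppressWarnings(as.integer(fields[2]))
      if (is.na(cnt) || cnt < 1) {
        stop(sprintf("row %d: count must be a positive integer", rows[i]))
      }
    }
    seqs[i] <- seq
    counts[i] <- cnt
    labels[i] <- if (length(fields) >= 3) fields[3] else NA_character_
  }
  data.frame(sequence = seqs, count = counts, label = labels)
}

#' Write a peptide table
#'
#' @param peptides Data.frame as returned by [read_peptide_table()].
#' @param path Output file path.
#' @param dialect Output dialect (see [read_peptide_table()]).
#' @export
write_peptide_table <- function(peptides, path,
                                dialect = c("plain", "delimited")) {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    writeLines(peptides$sequence, path)
  } else {
    lab <- peptides$label
    lines <- ifelse(is.na(lab),
                    paste(peptides$sequence, peptides$count, sep = ","),
                    paste(peptides$sequence, peptides$count, lab, sep = ","))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a protein collection from FASTA
#'
#' Standard multi-record FASTA; wrapped lines, CRLF endings and trailing blank
#' lines are tolerated. Sequences are uppercased with whitespace stripped. The
#' ambiguity character `X` is accepted and later makes any scan window that
#' contains it unscorable.
#'
#' @param source File path or literal FASTA text.
#' @return A data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(source) {
  if (is.character(source) && length(source) == 1 &&
      !grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    path <- source
  } else {
    lines <- read_source_lines(source)
    if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
      return(data.frame(id = character(), description = character(),
                        sequence = character()))
    }
    first <- lines[nzchar(trimws(lines))][1]
    if (!startsWith(trimws(first), ">")) {
      stop("not FASTA: first non-empty line must be a '>' header")
    }
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    return(data.frame(id = character(), description = character(),
                      sequence = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs))
}

#' Write protein records as FASTA
#'
#' @param proteins Data.frame with columns `id`, `description`, `sequence`.
#' @param path Output file path.
#' @param width Line-wrapping width.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(proteins))) {
    hdr <- if (nzchar(proteins$description[i])) {
      paste(proteins$id[i], proteins$description[i])
    } else {
      proteins$id[i]
    }
    writeLines(paste0(">", hdr), con)
    seq <- proteins$sequence[i]
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))), con)
  }
  invisible(path)
}

#' Write scan hits as tab-delimited text
#'
#' Columns `protein_id`, `start`, `end`, `p1_position`, `window`, `score`,
#' `mismatches`; coordinates 1-based inclusive; rows stably sorted by
#' `(protein_id, start)`.
#'
#' @param hits Data.frame of scan hits (see [scan_proteins()]).
#' @param path Output file path, or `NULL` to return the lines.
#' @return The output path (invisibly), or the text lines when `path = NULL`.
#' @export
write_hits <- function(hits, path = NULL) {
  cols <- c("protein_id", "start", "end", "p1_position", "window",
            "score", "mismatches")
  if (nrow(hits) > 0) {
    hits <- hits[order(hits$protein_id, hits$start), cols, drop = FALSE]
  } else {
    hits <- data.frame(protein_id = character(), start = integer(),
                       end = integer(), p1_position = integer(),
                       window = character(), score = numeric(),
                       mismatches = integer())
  }
  fmt_num <- function(x) ifelse(is.na(x), "NA", format(x, digits = 15))
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(hits) > 0) {
               paste(hits$protein_id, hits$start, hits$end, hits$p1_position,
                     hits$window, fmt_num(hits$score), fmt_num(hits$mismatches),
                     sep = "\t")
             })
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a scan-hit report written by [write_hits()]
#'
#' @param source File path or literal text.
#' @return Data.frame of hits.
#' @export
read_hits <- function(source) {
  lines <- read_source_lines(source)
  df <- read.table(text = paste(lines, collapse = "\n"), sep = "\t",
                   header = TRUE, colClasses = c(
                     protein_id = "character", start = "integer",
                     end = "integer", p1_position = "integer",
                     window = "character", score = "numeric",
                     mismatches = "numeric"))
  df
}

#' Write / read a position frequency matrix file
#'
#' Self-describing plain-text format recording the alphabet order, the subsite
#' labels, the pseudocount, the background composition, raw counts and the
#' pseudocount-smoothed frequencies. `read_matrix(write_matrix(m))` reproduces
#' frequencies exactly to at least 12 decimal places.
#'
#' @param pfm A [position_frequency_matrix()].
#' @param path Output path, or `NULL` to return lines.
#' @param background Background composition stored with the matrix.
#' @return `write_matrix()`: the path or lines; `read_matrix()`: the matrix.
#' @export
write_matrix <- function(pfm, path = NULL, background = NULL) {
  if (is.null(background)) {
    background <- rep(1 / 20, 20)
  }
  num <- function(x) format(x, digits = 17, scientific = TRUE)
  lines <- c(
    "# subsite position frequency matrix",
    paste("alphabet:", paste(aa_alphabet(), collapse = "")),
    paste("positions:", paste(pfm$positions, collapse = " ")),
    paste("n_sequences:", pfm$n_sequences),
    paste("pseudocount:", num(pfm$pseudocount)),
    paste("background:", paste(num(background), collapse = " ")),
    "frequencies:",
    vapply(seq_along(pfm$positions), function(j) {
      paste(pfm$positions[j], paste(num(pfm$frequencies[, j]), collapse = " "))
    }, character(1)),
    "counts:",
    vapply(seq_along(pfm$positions), function(j) {
      paste(pfm$positions[j], paste(num(pfm$counts[, j]), collapse = " "))
    }, character(1))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @param source File path or literal text of a matrix file.
#' @export
read_matrix <- function(source) {
  lines <- read_source_lines(source)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  field <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(hit) != 1) stop("matrix file: missing '", key, "' block")
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  alphabet <- strsplit(field("alphabet"), "")[[1]]
  if (!identical(alphabet, aa_alphabet())) {
    stop("matrix file: unexpected alphabet order")
  }
  positions <- strsplit(field("positions"), "\\s+")[[1]]
  check_window_positions(positions)
  n_seq <- as.integer(field("n_sequences"))
  pseudocount <- as.numeric(field("pseudocount"))
  background <- as.numeric(strsplit(field("background"), "\\s+")[[1]])
  parse_block <- function(name) {
    start <- grep(paste0("^", name, ":\\s*$"), lines)
    if (length(start) != 1) stop("matrix file: missing '", name, "' block")
    mat <- matrix(NA_real_, nrow = 20, ncol = length(positions),
                  dimnames = list(aa_alphabet(), positions))
    for (j in seq_along(positions)) {
      fields <- strsplit(trimws(lines[start + j]), "\\s+")[[1]]
      lab <- fields[1]
      if (!lab %in% positions) {
        stop("matrix file: unknown position label '", lab, "'")
      }
      mat[, lab] <- as.numeric(fields[-1])
    }
    mat
  }
  freq <- parse_block("frequencies")
  counts <- parse_block("counts")
  pfm <- position_frequency_matrix(counts = counts, pseudocount = pseudocount,
                                   n_sequences = n_seq)
  # stored frequencies are authoritative for round-trip fidelity
  pfm$frequencies <- freq
  attr(pfm, "background") <- background
  pfm
}
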