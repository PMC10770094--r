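#' Read a methylation bedGraph file
#'
#' Expects the 6-column extraction-tool dialect: `chrom`, `start`
#' (0-based), `end` (exclusive), integer percent methylation
#' (informational only), methylated count, unmethylated count, with an
#' optional 7th column of illegitimate-base counts (default 0). Counts are
#' authoritative; the percent column is never used for computation. An
#' optional leading `track` header is skipped. Malformed rows (wrong
#' column count, non-integer counts, `start >= end`) raise an error naming
#' the file and line.
#'
#' @param path File path.
#' @param reference Optional named character vector of sequences; when
#'   supplied, strand and context are recovered from the reference for
#'   1-bp records (forward C is `+`, forward G is `-`; 2-bp records are
#'   taken as merged CG on `+`).
#' @param context Context label carried from a per-context filename when
#'   no reference is given (default `NA`).
#' @param strand Strand carried when no reference is given.
#' @return Site record data frame: `chrom`, `start`, `end`, `strand`,
#'   `context`, `n_meth`, `n_unmeth`, `n_illegitimate`.
#' @export
read_bedgraph <- function(path, reference = NULL, context = NA_character_,
                          strand = NA_character_) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  is_track <- grepl("^track", lines)
  rows <- which(!is_track & nzchar(lines))
  parsed <- strsplit(lines[rows], "\t", fixed = TRUE)
  ncols <- lengths(parsed)
  bad <- which(!(ncols %in% c(6L, 7L)))
  if (length(bad))
    stopf("%s line %d: expected 6 or 7 tab-separated columns, found %d",
          path, rows[bad[1L]], ncols[bad[1L]])
  get_col <- function(i) vapply(parsed, function(x)
    if (length(x) >= i) x[[i]] else "0", character(1L))
  int_col <- function(i, name) {
    x <- get_col(i)
    bad <- which(!grepl("^[0-9]+$", x))
    if (length(bad))
      stopf("%s line %d: column %s is not a non-negative integer ('%s')",
            path, rows[bad[1L]], name, x[bad[1L]])
    as.integer(x)
  }
  chrom <- get_col(1L)
  start <- int_col(2L, "start")
  end <- int_col(3L, "end")
  int_col(4L, "percent")   # validated, never consumed
  n_meth <- int_col(5L, "n_meth")
  n_unmeth <- int_col(6L, "n_unmeth")
  n_illegitimate <- if (any(ncols == 7L)) int_col(7L, "n_illegitimate")
    else integer(length(rows))
  bad <- which(start >= end)
  if (length(bad))
    stopf("%s line %d: start >= end", path, rows[bad[1L]])
  out <- data.frame(chrom = chrom, start = start, end = end,
                    strand = strand, context = context,
                    n_meth = n_meth, n_unmeth = n_unmeth,
                    n_illegitimate = n_illegitimate,
                    stringsAsFactors = FALSE)
  if (!is.null(reference) && nrow(out)) {
    width2 <- out$end - out$start == 2L
    out$strand[width2] <- "+"
    out$context[width2] <- "CG"
    for (i in which(!width2)) {
      chr_seq <- reference[[out$chrom[i]]]
      if (is.null(chr_seq)) stopf("%s: unknown sequence '%s'",
                                  path, out$chrom[i])
      base <- substr(toupper(chr_seq), out$start[i] + 1L, out$start[i] + 1L)
      out$strand[i] <- if (base == "C") "+" else if (base == "G") "-"
        else stopf("%s: no cytosine at %s:%d", path, out$chrom[i],
                   out$start[i])
      out$context[i] <- classify_context(reference, out$chrom[i],
                                         out$start[i], out$strand[i])
    }
  }
  out
}

#' Write a methylation bedGraph file
#'
#' Records are sorted by `(chrom, start)` and written deterministically
#' (bit-identical output for identical input) with a `track` header. The
#' percent column is emitted as the rounded integer percentage (0 at zero
#' depth); the illegitimate-count column is appended only when any record
#' carries one.
#'
#' @param records Site record data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(records, path) {
  check_records(records)
  key <- paste(records$chrom, records$start)
  if (anyDuplicated(key))
    stopf("duplicate (chrom, start) keys: records are unsortable")
  ord <- order(records$chrom, records$start)
  records <- records[ord, , drop = FALSE]
  depth <- records$n_meth + records$n_unmeth
  percent <- ifelse(depth > 0, round(100 * records$n_meth / depth), 0)
  cols <- list(records$chrom, records$start, records$end,
               as.integer(percent), records$n_meth, records$n_unmeth)
  if (any(records$n_illegitimate > 0)) cols <- c(cols,
                                                 list(records$n_illegitimate))
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c("track type=bedGraph", body), path)
  invisible(path)
}

#' Read or write a phenotype table (TSV)
#'
#' Columns: `fish_id`, `genotype`, `rag1_area`, `gh_area`, and optionally
#' `eye_size`.
#'
#' @param path File path.
#' @return `read_phenotypes()`: the phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "genotype", "rag1_area", "gh_area")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  for (col in intersect(c("rag1_area", "gh_area", "eye_size"), names(out)))
    if (!is.numeric(out[[col]]))
      stopf("%s: column %s is not numeric", path, col)
  out
}

#' @param phenotypes Phenotype data frame.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSS list (BED6)
#'
#' @param path BED file with columns chrom, start, end, name, score,
#'   strand.
#' @return Data frame with those six columns; strand must be `+` or `-`.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  out <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  if (!all(out$strand %in% c("+", "-")))
    stopf("%s: TSS entries must carry strand '+' or '-'", path)
  if (any(out$start >= out$end)) stopf("%s: start >= end", path)
  out
}

#' @param tss TSS data frame (BED6 columns).
#' @rdname read_tss
#' @export
write_tss <- function(tss, path) {
  utils::write.table(tss[, c("chrom", "start", "end", "name", "score",
                             "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read or write a reference sequence (FASTA)
#'
#' @param path FASTA path.
#' @return `read_reference()`: named character vector of sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' @param reference Named character vector of sequences.
#' @rdname read_reference
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path,
                              width = 70L)
  invisible(path)
}
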