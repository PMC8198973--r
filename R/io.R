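## Batch I/O: EMPOP-style query tables and per-sample reports.

#' Read an EMPOP-style query table
#'
#' Tab-separated with header `sample_id`, `range` (e.g. `"16024-576"`),
#' `variants` (space-separated rCRS-relative tokens; empty means
#' reference-identical).
#'
#' @param path TSV file.
#' @param L reference length.
#' @return list of [haplotype()] objects.
#' @export
read_query_tsv <- function(path, L = 16569L) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "range", "variants")
  if (!all(need %in% names(tab)))
    stop("query table needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    parse_haplotype(tab$variants[i], parse_range(tab$range[i]),
                    tab$sample_id[i], L = L)
  })
}

#' Read query sequences from FASTA and align them to variant lists
#'
#' FASTA queries are full-range sequences; each is converted to a
#' haplotype by computing the best transcript against the
#' reference-identical haplotype and replaying it, so downstream code sees
#' the same representation as for TSV input.
#'
#' @param path FASTA file.
#' @param ref a [ref_sequence()].
#' @param range reading range the records cover (defaults to full).
#' @return list of [haplotype()] objects.
#' @export
read_query_fasta <- function(path, ref, range = full_range(ref)) {
  ss <- Biostrings::readBStringSet(path)
  lapply(seq_along(ss), function(i) {
    qsym <- strsplit(toupper(as.character(ss[[i]])), "")[[1]]
    seq_to_haplotype(qsym, names(ss)[i], ref, range)
  })
}

#' Convert a raw sequence to an rCRS-relative haplotype
#'
#' Aligns the sequence against the plain reference over `range` and
#' replays the resulting transcript on the reference-identical haplotype.
#'
#' @param symbols character vector (or string) of sequence symbols.
#' @param id sample identifier.
#' @param ref a [ref_sequence()].
#' @param range covered [reading_range()].
#' @return A [haplotype()].
#' @export
seq_to_haplotype <- function(symbols, id, ref, range = full_range(ref)) {
  if (length(symbols) == 1L) symbols <- strsplit(symbols, "")[[1]]
  refh <- haplotype(id, range, L = ref$length)
  t <- best_transcript_raw(symbols, refh, ref, range)
  apply_transcript(refh, t, ref)
}

#' Tabulate haplogrouping/alignment results for a batch of queries
#'
#' @param results list as returned by [align_query()], one per query.
#' @param queries the corresponding input haplotypes.
#' @return data.frame with per-sample rank-1/rank-2 names, MRCA estimates,
#'   cost, essential-private count, transcript and final alignment tokens.
#' @export
report_table <- function(results, queries) {
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]; q <- queries[[i]]
    best <- r$search$rank1[[1]]
    data.frame(
      sample_id = q$sample_id,
      range = format(q$range),
      rank1 = paste(r$search$rank1_names, collapse = ","),
      rank2 = paste(r$search$rank2_names, collapse = ","),
      mrca_rank1 = r$search$mrca_rank1,
      mrca_rank2 = r$search$mrca_rank2,
      cost = best$cost,
      n_essential_privates = best$n_essential,
      transcript = serialize_transcript(r$transcript),
      alignment = format(r$alignment),
      stringsAsFactors = FALSE)
  }))
}

#' Write a report as TSV or JSON
#' @param tab data.frame from [report_table()].
#' @param path output file.
#' @param format `"tsv"` or `"json"` (JSON mirrors the TSV columns 1:1).
#' @export
write_report <- function(tab, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
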