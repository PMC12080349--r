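#' Read a FASTA file
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Only the coordinate columns are used (seqid, start, end, strand);
#' attributes are treated as opaque.
#'
#' @param path file path.
#' @param types feature types to keep (default `"gene"` and `"CDS"`; NULL
#'   keeps all).
#' @return data.frame with `contig`, `start`, `end`, `strand`, `type`.
#' @export
read_gff3 <- function(path, types = c("gene", "CDS")) {
  g <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(g)),
                   start = BiocGenerics::start(g), end = BiocGenerics::end(g),
                   strand = as.character(BiocGenerics::strand(g)),
                   type = as.character(g$type), stringsAsFactors = FALSE)
  if (!is.null(types)) df <- df[df$type %in% types, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write gene features to a GFF3 file
#' @param genes data.frame with `contig`, `start`, `end` and optionally
#'   `strand`, `type`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = if ("strand" %in% names(genes)) genes$strand else "+",
    type = if ("type" %in% names(genes)) genes$type else "gene")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write locus descriptors to JSON
#'
#' Repeat and spacer intervals are written 1-based inclusive.
#'
#' @param loci list of `crispr_locus` objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_locus_json <- function(loci, path) {
  recs <- lapply(loci, function(l) list(
    id = l$id, subtype = l$subtype, contig = l$contig_id, strand = l$strand,
    repeats = l$repeats, consensus = l$consensus,
    tracrRNA = if (is.null(l$tracrRNA)) NULL else l$tracrRNA))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read locus descriptors from JSON plus contig FASTA
#'
#' @param json_path descriptor file written by [write_locus_json()] (or
#'   equivalent): fields `id`, `subtype`, `contig`, `strand`, `repeats`
#'   (1-based inclusive `start`/`end`), optional `consensus`, `tracrRNA`.
#' @param contigs named character vector of contig sequences (e.g. from
#'   [read_fasta()]).
#' @return list of `crispr_locus` objects.
#' @export
#' @examples
#' ex <- function(f) system.file("extdata", f, package = "ecrmech")
#' loci <- read_locus_json(ex("example_loci.json"),
#'                         read_fasta(ex("example_contigs.fasta")))
#' loci[[1]]
read_locus_json <- function(json_path, contigs) {
  recs <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  if (is.data.frame(recs)) recs <- split(recs, seq_len(nrow(recs)))
  lapply(recs, function(r) {
    r <- as.list(r)
    reps <- as.data.frame(if (is.list(r$repeats) && !is.data.frame(r$repeats))
      r$repeats[[1]] else r$repeats)
    crispr_locus(id = r$id[[1]], contig = contigs[[r$contig[[1]]]],
                 repeats = reps, strand = r$strand[[1]],
                 subtype = r$subtype[[1]],
                 tracrRNA = if (is.null(r$tracrRNA) || all(is.na(r$tracrRNA))) NULL
                            else r$tracrRNA[[1]],
                 consensus = if (is.null(r$consensus) || all(is.na(r$consensus))) NULL
                             else r$consensus[[1]],
                 contig_id = r$contig[[1]])
  })
}

# TSV writer with '#'-prefixed metadata lines
.write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
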