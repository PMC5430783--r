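#' Transcript models
#'
#' A `transcript_model` is a stranded, possibly multi-exon transcript on one
#' chromosome: the unit of the whole analysis. Exons are held as a sorted,
#' disjoint 0-based half-open table; transcript length is the sum of exon
#' widths.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`; unstranded transcripts are rejected.
#' @param exons data.frame with integer `start`, `end` columns (0-based
#'   half-open), sorted by start and pairwise disjoint.
#' @param biotype one of `"protein_coding"`, `"lincRNA"`, `"unknown"`.
#' @param source provenance: `"assembly"`, `"ensembl_ref"`,
#'   `"zflncrnapedia_ref"`.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             biotype = "unknown", source = "assembly") {
  if (!strand %in% c("+", "-"))
    stop(sprintf("transcript %s: strand must be '+' or '-'", transcript_id))
  if (!biotype %in% c("protein_coding", "lincRNA", "unknown"))
    stop("biotype must be protein_coding, lincRNA or unknown")
  if (!source %in% c("assembly", "ensembl_ref", "zflncrnapedia_ref"))
    stop("unknown source tag")
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  validate_exon_table(exons)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 biotype = biotype, source = source),
            class = "transcript_model")
}

#' Transcript length (sum of exon widths)
#' @param model a `transcript_model`.
#' @return integer length in nucleotides.
#' @export
transcript_length <- function(model) sum(model$exons$end - model$exons$start)

#' Genomic span of a transcript
#' @param model a `transcript_model`.
#' @return integer vector `c(start, end)` (0-based half-open).
#' @export
transcript_span <- function(model)
  c(model$exons$start[1L], model$exons$end[nrow(model$exons)])

#' Transcription start site
#'
#' The first transcribed base: the leftmost exon base on `+`, the rightmost
#' on `-` (0-based position of the base itself).
#' @param model a `transcript_model`.
#' @return integer position.
#' @export
transcript_tss <- function(model) {
  sp <- transcript_span(model)
  if (model$strand == "+") sp[1L] else sp[2L] - 1L
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s%s %d exon(s), %d nt, %s/%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), transcript_length(x), x$biotype, x$source))
  invisible(x)
}

#' Extract the spliced transcript sequence from a genome
#'
#' Concatenates the exon sequences in ascending genomic order; on the `-`
#' strand the reverse complement of that concatenation is returned, so the
#' result always reads 5' to 3' in transcript orientation.
#'
#' @param model a `transcript_model`.
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @return uppercase character string over `{A,C,G,T,N}`.
#' @export
extract_spliced_sequence <- function(model, genome) {
  if (!model$chrom %in% names(genome))
    stop(sprintf("chromosome '%s' absent from genome", model$chrom))
  chrom_len <- Biostrings::width(genome[model$chrom])
  if (any(model$exons$end > chrom_len))
    stop(sprintf("transcript %s: exon beyond end of %s (%d)",
                 model$transcript_id, model$chrom, chrom_len))
  chrom_seq <- genome[[model$chrom]]
  pieces <- vapply(seq_len(nrow(model$exons)), function(i) {
    as.character(Biostrings::subseq(chrom_seq,
                                    start = model$exons$start[i] + 1L,
                                    end = model$exons$end[i]))
  }, character(1L))
  seq <- Biostrings::DNAString(paste(pieces, collapse = ""))
  if (model$strand == "-") seq <- Biostrings::reverseComplement(seq)
  toupper(as.character(seq))
}
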