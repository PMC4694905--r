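#' Construct a transcript model
#'
#' Exon structure plus CDS placement for one transcript. Exons are
#' 1-based inclusive genomic intervals sorted by genomic start and
#' non-overlapping; `cds_start` / `cds_end` are 1-based positions in
#' transcript (mRNA) coordinates; `cds_sequence` is the sense-strand CDS
#' (what the ribosome reads), so for a minus-strand gene it is the
#' reverse complement of the genomic reference.
#'
#' @param transcript_id string.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (genomic, 1-based,
#'   inclusive).
#' @param cds_start,cds_end CDS bounds in transcript coordinates.
#' @param cds_sequence CDS nucleotide string; length must equal
#'   `cds_end - cds_start + 1`.
#' @param complete whether the CDS is complete (default); a complete CDS
#'   must have length divisible by 3, start with ATG and end with a stop
#'   codon. Partial models (coordinate fixtures) may set this to FALSE.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, strand, exons,
                             cds_start, cds_end, cds_sequence,
                             complete = TRUE) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap or touch; intervals must be disjoint")
  tx_len <- sum(exons$end - exons$start + 1)
  cds_len <- cds_end - cds_start + 1
  if (cds_end > tx_len || cds_start < 1 || cds_len < 3)
    stop("CDS bounds fall outside the transcript")
  cds_sequence <- toupper(cds_sequence)
  if (nchar(cds_sequence) != cds_len)
    stop("cds_sequence length does not match CDS bounds")
  if (complete) {
    if (cds_len %% 3 != 0)
      stop("a complete CDS must have length divisible by 3")
    last <- substr(cds_sequence, cds_len - 2, cds_len)
    if (substr(cds_sequence, 1, 3) != "ATG" ||
        !last %in% c("TAA", "TAG", "TGA"))
      stop("a complete CDS must start with ATG and end with a stop codon")
  }
  structure(list(transcript_id = transcript_id, strand = strand,
                 exons = exons, cds_start = cds_start, cds_end = cds_end,
                 cds_sequence = cds_sequence),
            class = "transcript_model")
}

#' Map a CDS position to its codon
#'
#' Pure arithmetic: codon index = floor((pos - 1) / 3) + 1, offset
#' within the codon = ((pos - 1) mod 3) + 1. CDS position 802 sits at
#' the first base of codon 268.
#'
#' @param cds_pos 1-based CDS position.
#' @return list with `codon_index`, `codon_offset` (1, 2 or 3).
#' @export
cds_to_codon <- function(cds_pos) {
  if (any(cds_pos < 1)) stop("cds_pos must be >= 1")
  list(codon_index = (cds_pos - 1) %/% 3 + 1,
       codon_offset = (cds_pos - 1) %% 3 + 1)
}

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("cannot translate codon: ", codon)
  aa
}

#' Apply a single-base CDS substitution
#'
#' Extracts the affected codon from the CDS, substitutes the alternate
#' base, translates both codons with the standard genetic code, and
#' formats the simplified HGVS substitution names, e.g. `c.802C > T` /
#' `p.R268C`.
#'
#' @param t a [transcript_model()].
#' @param cds_pos 1-based CDS position of the substitution.
#' @param alt_base the alternate base (CDS sense strand).
#' @return list of class `coding_effect`: `cds_pos`, `codon_index`,
#'   `codon_offset`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect_class` (`synonymous` / `missense` / `nonsense`), `hgvs_c`,
#'   `hgvs_p`.
#' @export
apply_cds_substitution <- function(t, cds_pos, alt_base) {
  cds_len <- nchar(t$cds_sequence)
  if (cds_pos < 1 || cds_pos > cds_len)
    stop("cds_pos ", cds_pos, " beyond CDS of length ", cds_len)
  alt_base <- toupper(alt_base)
  ref_base <- substr(t$cds_sequence, cds_pos, cds_pos)
  if (ref_base == alt_base)
    stop("alternate base equals the reference base (", ref_base,
         ") at c.", cds_pos)
  cod <- cds_to_codon(cds_pos)
  c0 <- (cod$codon_index - 1) * 3 + 1
  ref_codon <- substr(t$cds_sequence, c0, c0 + 2)
  alt_codon <- ref_codon
  substr(alt_codon, cod$codon_offset, cod$codon_offset) <- alt_base
  ref_aa <- .translate_codon(ref_codon)
  alt_aa <- .translate_codon(alt_codon)
  effect <- if (ref_aa == alt_aa) "synonymous"
            else if (alt_aa == "*" && ref_aa != "*") "nonsense"
            else "missense"
  structure(list(
    cds_pos = cds_pos, codon_index = cod$codon_index,
    codon_offset = cod$codon_offset,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa, effect_class = effect,
    hgvs_c = sprintf("c.%d%s > %s", cds_pos, ref_base, alt_base),
    hgvs_p = sprintf("p.%s%d%s", ref_aa, cod$codon_index, alt_aa)),
    class = "coding_effect")
}

# Genomic positions of the transcript in transcription order (5' -> 3').
.tx_positions <- function(t) {
  pos <- unlist(lapply(seq_len(nrow(t$exons)),
                       function(i) t$exons$start[i]:t$exons$end[i]))
  if (t$strand == "-") rev(pos) else pos
}

#' Map a genomic position to a CDS position
#'
#' Walks the exons in transcription order (3'-to-5' genomic order for a
#' minus-strand transcript) and subtracts the 5' UTR offset. Positions in
#' introns or UTRs come back tagged, not as errors; a position outside
#' the transcript span is an error.
#'
#' @param t a [transcript_model()].
#' @param gpos 1-based genomic position.
#' @return list with `type` (`"cds"`, `"utr5"`, `"utr3"` or
#'   `"intronic"`) and `cds_pos` (`NA` unless `type == "cds"`).
#' @export
genomic_to_cds <- function(t, gpos) {
  span <- range(t$exons$start, t$exons$end)
  if (gpos < span[1] || gpos > span[2])
    stop("genomic position ", gpos, " outside transcript span ",
         span[1], "-", span[2])
  tx <- .tx_positions(t)
  tpos <- match(gpos, tx)
  if (is.na(tpos)) return(list(type = "intronic", cds_pos = NA_integer_))
  if (tpos < t$cds_start) return(list(type = "utr5", cds_pos = NA_integer_))
  if (tpos > t$cds_end) return(list(type = "utr3", cds_pos = NA_integer_))
  list(type = "cds", cds_pos = tpos - t$cds_start + 1L)
}

#' Map a CDS position back to the genome
#'
#' Inverse of [genomic_to_cds()] on coding positions.
#'
#' @param t a [transcript_model()].
#' @param cds_pos 1-based CDS position.
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(t, cds_pos) {
  cds_len <- t$cds_end - t$cds_start + 1
  if (cds_pos < 1 || cds_pos > cds_len)
    stop("cds_pos ", cds_pos, " beyond CDS of length ", cds_len)
  tx <- .tx_positions(t)
  tx[t$cds_start + cds_pos - 1]
}

#' Project an allele across strands
#'
#' Identity on the forward strand; Watson-Crick complement on the
#' reverse strand — a forward-strand G/A polymorphism is a C/T change on
#' a reverse-strand transcript.
#'
#' @param base one of A, C, G, T.
#' @param strand `"+"` or `"-"`.
#' @return the projected base.
#' @export
complement_strand_allele <- function(base, strand) {
  base <- toupper(base)
  if (!base %in% c("A", "C", "G", "T"))
    stop("base must be one of A, C, G, T; got ", base)
  stopifnot(strand %in% c("+", "-"))
  if (strand == "+") return(base)
  c(A = "T", C = "G", G = "C", T = "A")[[base]]
}

#' Read transcript fixtures from TSV + FASTA
#'
#' The TSV has one row per transcript: `transcript_id`, `strand`,
#' `exons` (semicolon-separated `start-end` intervals), `cds_start`,
#' `cds_end`. CDS sequences come from a FASTA file keyed by transcript
#' id.
#'
#' @param tsv_path transcript structure table.
#' @param fasta_path FASTA of CDS sequences.
#' @return named list of [transcript_model()]s.
#' @export
read_transcript_models <- function(tsv_path, fasta_path) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    iv <- strsplit(strsplit(tab$exons[i], ";", fixed = TRUE)[[1]], "-")
    exons <- data.frame(start = as.integer(vapply(iv, `[`, "", 1)),
                        end = as.integer(vapply(iv, `[`, "", 2)))
    id <- tab$transcript_id[i]
    if (!id %in% names(seqs))
      stop("no CDS sequence for transcript ", id)
    transcript_model(id, tab$strand[i], exons,
                     tab$cds_start[i], tab$cds_end[i],
                     as.character(seqs[[id]]),
                     complete = if ("complete" %in% names(tab))
                       as.logical(tab$complete[i]) else TRUE)
  })
  names(out) <- tab$transcript_id
  out
}
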