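# Coding-sequence consequence annotation of candidate null mutations:
# frameshifts, premature stop codons, in-frame indels.

#' Annotate a variant within a coding sequence
#'
#' Applies the variant to the CDS, translates in frame from the CDS start
#' with the standard nuclear code, and classifies the consequence. A pure
#' indel is a frameshift iff its length is not divisible by 3; a premature
#' stop is any in-frame stop codon before the final codon of the mutated
#' sequence. Offsets are reported on the mutated transcript: `stop_offset_cds`
#' is the distance in bp from the CDS start to the last base of the new stop
#' codon, and `stop_offset_tx` adds the 5' UTR length, giving the
#' "bp from the transcription start site" style of reporting.
#'
#' @param cds coding sequence (character or `DNAString`); must begin with ATG
#'   and have length divisible by 3
#' @param variant list with `pos` (1-based position in the CDS), `ref` and
#'   `alt` allele strings (VCF style; equal lengths = substitution, otherwise
#'   indel). `ref` must match the CDS at `pos`.
#' @param utr5_len length of the 5' UTR in bp (default 0)
#' @return list of class `mutation_annotation`: `consequence` (one of
#'   `frameshift_premature_stop`, `frameshift_no_stop`, `inframe_deletion`,
#'   `inframe_insertion`, `premature_stop_no_frameshift`, `none`),
#'   `stop_offset_cds`, `stop_offset_tx` (NA when no premature stop),
#'   `indel_len`, `aa_change` (amino acids lost/gained for in-frame indels),
#'   and the translated mutant protein.
#' @export
annotate_variant <- function(cds, variant, utr5_len = 0L) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3")
  if (substr(cds, 1, 3) != "ATG") stop("CDS must begin with ATG")
  ref <- toupper(variant$ref)
  alt <- toupper(variant$alt)
  pos <- as.integer(variant$pos)
  if (pos < 1 || pos + nchar(ref) - 1L > n) {
    stop("variant outside CDS")
  }
  if (substr(cds, pos, pos + nchar(ref) - 1L) != ref) {
    stop("variant ref allele does not match CDS at position ", pos)
  }
  mutated <- paste0(substr(cds, 1, pos - 1L), alt,
                    substr(cds, pos + nchar(ref), n))
  indel_len <- nchar(alt) - nchar(ref)
  frameshift <- indel_len %% 3L != 0L

  translate_frame <- function(s) {
    usable <- 3L * (nchar(s) %/% 3L)
    if (usable == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1, usable)), no.init.codon = TRUE))
  }
  prot <- translate_frame(mutated)
  n_codons <- nchar(prot)
  stop_idx <- regexpr("*", prot, fixed = TRUE)
  stop_idx <- if (stop_idx > 0) as.integer(stop_idx) else NA_integer_
  premature <- !is.na(stop_idx) && stop_idx < n_codons

  consequence <- if (frameshift) {
    if (premature) "frameshift_premature_stop" else "frameshift_no_stop"
  } else if (premature) {
    "premature_stop_no_frameshift"
  } else if (indel_len < 0L) {
    "inframe_deletion"
  } else if (indel_len > 0L) {
    "inframe_insertion"
  } else {
    "none"
  }
  aa_change <- if (!frameshift && indel_len != 0L) abs(indel_len) %/% 3L
               else NA_integer_
  stop_offset_cds <- if (premature) 3L * stop_idx else NA_integer_
  structure(
    list(consequence = consequence,
         stop_offset_cds = stop_offset_cds,
         stop_offset_tx = if (is.na(stop_offset_cds)) NA_integer_
                          else utr5_len + stop_offset_cds,
         indel_len = indel_len,
         aa_change = aa_change,
         protein = prot,
         variant = variant),
    class = "mutation_annotation")
}

#' @export
print.mutation_annotation <- function(x, ...) {
  cat("<mutation_annotation>", x$consequence, "\n")
  if (!is.na(x$stop_offset_cds)) {
    cat("  premature stop:", x$stop_offset_cds, "bp from CDS start (",
        x$stop_offset_tx, "bp from transcription start)\n")
  }
  if (!is.na(x$aa_change)) cat("  amino acids affected:", x$aa_change, "\n")
  invisible(x)
}

#' Assemble a CDS from a transcript model
#'
#' Concatenates exon CDS spans (1-based inclusive coordinates on the genome
#' sequence) in genomic order and reverse-complements the result for
#' minus-strand transcripts.
#'
#' @param genome_seq the chromosome/scaffold sequence (character or
#'   `DNAString`)
#' @param spans data.frame with columns `start`, `end` (1-based inclusive)
#' @param strand "+" or "-"
#' @return CDS as a character string
#' @export
cds_from_model <- function(genome_seq, spans, strand = "+") {
  genome_seq <- as.character(genome_seq)
  spans <- spans[order(spans$start), , drop = FALSE]
  parts <- substring(genome_seq, spans$start, spans$end)
  cds <- paste(parts, collapse = "")
  if (strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  cds
}

#' Read a GFF-like transcript model TSV
#'
#' Expects columns chrom, start, end, strand, feature (rows with feature
#' "CDS" are the coding spans; a "five_prime_UTR" row, if present, supplies
#' the 5' UTR length).
#'
#' @param path TSV with header
#' @return list(spans = CDS spans data.frame, strand, utr5_len)
#' @export
read_transcript_model <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  cds <- df[df$feature == "CDS", , drop = FALSE]
  utr <- df[df$feature == "five_prime_UTR", , drop = FALSE]
  utr5 <- if (nrow(utr)) sum(utr$end - utr$start + 1L) else 0L
  list(spans = cds[, c("start", "end")], strand = cds$strand[1],
       utr5_len = utr5)
}

#' Write mutation annotations as TSV
#' @param annotations list of `mutation_annotation` objects
#' @param path output path
#' @export
write_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    data.frame(pos = a$variant$pos, ref = a$variant$ref, alt = a$variant$alt,
               consequence = a$consequence, indel_len = a$indel_len,
               stop_offset_cds = a$stop_offset_cds,
               stop_offset_tx = a$stop_offset_tx, aa_change = a$aa_change,
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
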