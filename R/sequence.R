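#' Eisenberg consensus hydrophobicity scale
#'
#' The normalised consensus hydrophobicity values of Eisenberg, Schwarz,
#' Komaromy and Wall (1984, J. Mol. Biol. 179:125-142), one value per
#' standard amino acid; more positive means more hydrophobic. The transcribed
#' table is validated on load: 20 entries whose sum is 0.00 (the scale is
#' normalised to zero mean at 2-decimal precision).
#'
#' @return named numeric vector over the 20 one-letter codes.
#' @export
eisenberg_scale <- function() {
  sc <- c(
    A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
    Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
    L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
    S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08
  )
  stopifnot(length(sc) == 20L, abs(sum(sc)) < 1e-9)
  sc
}

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Hydrophobicity index of a residue set
#'
#' Plain sum of per-residue scale values; by convention a region's index is
#' the sum over its residues (a more positive sum means a more hydrophobic
#' region). Residues may be given as one-letter or three-letter codes
#' (case-insensitive); trailing residue numbers (e.g. "Ile99") are ignored.
#'
#' @param residues character vector of residue codes.
#' @param scale named numeric scale (default [eisenberg_scale()]).
#' @return numeric sum (0 for an empty set).
#' @export
hydrophobicity_index <- function(residues, scale = eisenberg_scale()) {
  if (length(residues) == 0L) return(0)
  code <- toupper(sub("[0-9]+$", "", trimws(residues)))
  three <- nchar(code) == 3L
  code[three] <- AA3_TO_1[code[three]]
  unknown <- is.na(code) | !code %in% names(scale)
  if (any(unknown)) {
    stop("unknown residue code: ", residues[which(unknown)[1L]])
  }
  sum(scale[code])
}

#' Pairwise global alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment of two protein sequences under a substitution
#' matrix with affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`), computed by
#' [Biostrings::pairwiseAlignment()]. Defaults are BLOSUM62 with open 10 and
#' extend 0.5, the EMBOSS-needle-like convention.
#'
#' @param a,b protein sequences (character scalars, 20-letter alphabet; X
#'   tolerated and scored by the matrix).
#' @param substitution_matrix matrix name understood by Biostrings ("BLOSUM62")
#'   or an actual matrix.
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @return object of class `pairwise_alignment`: list with `a_aligned`,
#'   `b_aligned` (gapped strings of equal length) and `score`.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- toupper(gsub("[[:space:]]", "", a))
  b <- toupper(gsub("[[:space:]]", "", b))
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  out <- list(
    a_aligned = as.character(Biostrings::alignedPattern(pa)),
    b_aligned = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
  stopifnot(nchar(out$a_aligned) == nchar(out$b_aligned),
            gsub("-", "", out$a_aligned) == a,
            gsub("-", "", out$b_aligned) == b)
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, width = 60L, ...) {
  n <- nchar(x$a_aligned)
  cat("<pairwise_alignment> length ", n, ", score ", x$score, "\n", sep = "")
  for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    ca <- strsplit(substr(x$a_aligned, s, e), "")[[1]]
    cb <- strsplit(substr(x$b_aligned, s, e), "")[[1]]
    mid <- ifelse(ca == cb & ca != "-", "|", " ")
    cat(substr(x$a_aligned, s, e), "\n", paste(mid, collapse = ""), "\n",
        substr(x$b_aligned, s, e), "\n\n", sep = "")
  }
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' @param aln a [global_align()] result.
#' @param denominator "alignment_length" (identical columns over all columns,
#'   the default) or "shorter_sequence".
#' @return percent identity, rounded to 1 decimal.
#' @export
percent_identity <- function(aln,
                             denominator = c("alignment_length",
                                             "shorter_sequence")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(aln$a_aligned, "")[[1]]
  cb <- strsplit(aln$b_aligned, "")[[1]]
  ident <- sum(ca == cb & ca != "-")
  den <- switch(denominator,
    alignment_length = length(ca),
    shorter_sequence = min(sum(ca != "-"), sum(cb != "-"))
  )
  round(100 * ident / den, 1)
}

#' All-pairs percent-identity matrix
#'
#' @param seqs named character vector of sequences.
#' @param ... passed to [global_align()] / [percent_identity()].
#' @return symmetric numeric matrix (diagonal 100).
#' @export
identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  m <- diag(100, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pid <- percent_identity(global_align(seqs[[i]], seqs[[j]], ...))
      m[i, j] <- m[j, i] <- pid
    }
  }
  m
}
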