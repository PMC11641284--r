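#' Named residue regions
#'
#' A region set maps region labels to lists of inclusive residue-index
#' ranges. Labels must be unique; ranges are `c(from, to)` pairs (or a
#' two-column matrix of such pairs).
#'
#' @param ... named arguments, each a `c(from, to)` range or a matrix of
#'   ranges (one per row).
#' @return object of class `region_set`: named list of two-column matrices.
#' @export
region_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 0L) stop("a region set needs at least one region")
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("every region must be named")
  }
  if (anyDuplicated(names(entries))) stop("region labels must be unique")
  out <- lapply(entries, function(r) {
    m <- if (is.matrix(r)) r else matrix(as.numeric(r), ncol = 2L, byrow = TRUE)
    storage.mode(m) <- "integer"
    if (ncol(m) != 2L || any(m[, 1L] > m[, 2L]) || any(m < 1L)) {
      stop("region ranges must be c(from, to) pairs with 1 <= from <= to")
    }
    colnames(m) <- c("from", "to")
    m
  })
  class(out) <- "region_set"
  out
}

#' Residues covered by one region
#' @param regions a [region_set()].
#' @param label region label.
#' @return integer vector of residue indices.
#' @export
region_residues <- function(regions, label) {
  if (!label %in% names(regions)) stop("no region named '", label, "'")
  m <- regions[[label]]
  sort(unique(unlist(lapply(seq_len(nrow(m)),
                            function(i) seq.int(m[i, 1L], m[i, 2L])))))
}

#' Check that a region set fits a residue range
#' @param regions a [region_set()].
#' @param residues residue indices available (e.g. from a topology).
#' @return `TRUE` invisibly; errors naming the offending region otherwise.
#' @export
validate_regions <- function(regions, residues) {
  for (lab in names(regions)) {
    miss <- setdiff(region_residues(regions, lab), residues)
    if (length(miss) > 0L) {
      stop("region '", lab, "' includes residue(s) outside the structure: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Default IL-18 binding-region definitions
#'
#' Mature-sequence residue ranges of human IL-18's receptor-binding regions:
#' binding site I (the Glu31-Thr45 large loop and the Glu130-Phe134 small
#' loop), binding site II (Lys53-Met60), binding site III (Gly108-Lys112 and
#' Asp142-Met150) and the Glu85-Ile100 loop that lids the residue-63 cavity.
#' The two beta-sheets flanking site II (Thr45-Tyr52, Ala61-Cys68) are kept
#' as a separate entry so the classified "site II" stays the Lys53-Met60
#' region itself.
#'
#' @return a [region_set()].
#' @export
il18_regions <- function() {
  region_set(
    site_I = rbind(c(31L, 45L), c(130L, 134L)),
    site_II = c(53L, 60L),
    site_II_sheets = rbind(c(45L, 52L), c(61L, 68L)),
    site_III = rbind(c(108L, 112L), c(142L, 150L)),
    loop_85_100 = c(85L, 100L)
  )
}

#' The residue-63 cavity of wild-type IL-18
#'
#' Thr63 plus the twelve residues surrounding it at the core beta-barrel and
#' the Glu85-Ile100 loop. The grouping follows the structural-figure
#' convention (Tyr52 grouped with the hydrophilic residues Ser50, Ser65 and
#' Thr73; elsewhere it is sometimes listed as hydrophobic - the index sum is
#' unaffected either way).
#'
#' @return data.frame with columns `residue` (e.g. "Ile48"), `resno` and
#'   `group` ("hydrophobic"/"hydrophilic"/"focal").
#' @export
il18_cavity63 <- function() {
  data.frame(
    residue = c("Thr63", "Ile48", "Ile49", "Ser50", "Tyr52", "Val62", "Ile64",
                "Ser65", "Thr73", "Pro88", "Ile92", "Ile99", "Ile100"),
    resno = c(63L, 48L, 49L, 50L, 52L, 62L, 64L, 65L, 73L, 88L, 92L, 99L,
              100L),
    group = c("focal", "hydrophobic", "hydrophobic", "hydrophilic",
              "hydrophilic", "hydrophobic", "hydrophobic", "hydrophilic",
              "hydrophilic", "hydrophobic", "hydrophobic", "hydrophobic",
              "hydrophobic"),
    stringsAsFactors = FALSE
  )
}
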