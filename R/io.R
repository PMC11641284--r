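#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL blocks delimit frames; a file without MODEL records yields a
#' one-frame trajectory. Atom order must be identical across models; a model
#' whose atom count differs from the first is reported as a parse error naming
#' the model. Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param path PDB file.
#' @param offset integer added to the file's residue numbers so that indices
#'   follow the mature-sequence convention (default 0: numbers taken as-is).
#' @param label label stored on the topology (default: file name).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, offset = 0L, label = basename(path)) {
  if (!file.exists(path)) stop("cannot read trajectory: no such file: ", path)
  check_model_atom_counts(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    serial  = as.integer(at$eleno),
    name    = trimws(at$elety),
    elem    = trimws(ifelse(is.na(at$elesy), "", at$elesy)),
    resno   = as.integer(at$resno) + as.integer(offset),
    resname = trimws(at$resid),
    stringsAsFactors = FALSE
  )
  blank <- !nzchar(atoms$elem)
  if (any(blank)) atoms$elem[blank] <- guess_element(atoms$name[blank])
  xyz <- pdb$xyz                       # n_frames x 3N matrix
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  arr <- array(NA_real_, dim = c(na, 3L, nf))
  for (f in seq_len(nf)) {
    arr[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  topo <- structure3d(atoms, arr[, , 1L, drop = TRUE], label = label)
  trajectory(topo, arr)
}

# Fail fast, naming the offending MODEL, before handing the file to bio3d
# (which silently mis-stacks ragged models).
check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) < 2L) return(invisible(TRUE))
  model_of <- findInterval(which(is_atom), model_starts)
  counts <- tabulate(model_of, nbins = length(model_starts))
  bad <- which(counts != counts[1L])
  if (length(bad) > 0L) {
    stop("model ", bad[1L], " has ", counts[bad[1L]],
         " atoms but model 1 has ", counts[1L],
         ": all MODEL blocks must share one topology")
  }
  invisible(TRUE)
}

# PDB element from the atom-name convention: strip leading digits, first letter.
guess_element <- function(name) {
  n <- sub("^[0-9]+", "", toupper(trimws(name)))
  substr(n, 1L, 1L)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; a one-frame trajectory is written as a
#' plain single-model file without MODEL records (the reader yields one frame
#' for it either way). Coordinates are written at the PDB fixed-format
#' precision of 3 decimals, so a write/read round trip preserves them to
#' 0.001 Angstrom.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  at <- traj$topology$atoms
  xyz_flat <- matrix(NA_real_, nrow = nf, ncol = 3L * nrow(at))
  for (f in seq_len(nf)) xyz_flat[f, ] <- as.vector(t(traj$xyz[, , f]))
  bio3d::write.pdb(
    file = path,
    xyz = xyz_flat,
    resno = at$resno,
    resid = at$resname,
    eleno = at$serial,
    elety = at$name,
    elesy = at$elem,
    chain = "A"
  )
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return data.frame with columns `id` (full header text) and `seq`
#'   (upper-cased, whitespace-free sequence), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: no such file: ", path)
  set <- suppressWarnings(Biostrings::readAAStringSet(path))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("FASTA record '", names(set)[which(!nzchar(seqs))[1L]],
         "' has an empty sequence")
  }
  data.frame(id = names(set), seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Fetch sequences from UniProt (network helper)
#'
#' Downloads `<accession>.fasta` records from the UniProt REST service into
#' one file. Requires network access; all offline analyses take a local FASTA
#' path instead.
#'
#' @param accessions character vector of UniProt accessions.
#' @param dest output FASTA path.
#' @return `dest`, invisibly.
#' @export
fetch_uniprot_fasta <- function(accessions, dest) {
  urls <- paste0("https://rest.uniprot.org/uniprotkb/", accessions, ".fasta")
  chunks <- character(0)
  for (u in urls) {
    con <- url(u)
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    chunks <- c(chunks, readLines(con, warn = FALSE))
    close(con)
  }
  writeLines(chunks, dest)
  invisible(dest)
}

#' Write a table as tab-separated values
#'
#' Plain TSV without quoting or row names: the exchange format for all
#' pipeline outputs (profiles, occupancy tables, summaries).
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
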