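#' Alpha-carbon chain structure
#'
#' The universal input of the toolkit: an ordered chain of C-alpha
#' coordinates with residue identifiers. Residues are kept in file order
#' and all of the alignment machinery refers to them by their 1-based
#' position in this order, never by author residue numbers (insertion
#' codes and numbering gaps are preserved as metadata only).
#'
#' @param xyz `n x 3` numeric matrix of C-alpha coordinates (Angstroms),
#'   all finite.
#' @param id identifier, conventionally PDB id plus chain (e.g. `"1opyA"`).
#' @param resno integer author residue numbers (default `1:n`).
#' @param ins single-character insertion codes (default blank).
#' @param aa one-letter amino-acid codes (default `"A"`).
#' @param chain chain identifier (single character).
#' @return An object of class `structure3d`.
#' @examples
#' s <- structure3d(cbind(3.8 * (0:3), 0, 0), id = "toy")
#' nres(s)
#' @export
structure3d <- function(xyz, id = "structure", resno = NULL, ins = NULL,
                        aa = NULL, chain = "A") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(ncol(xyz) == 3L)
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(ins)) ins <- rep("", n)
  if (is.null(aa)) aa <- rep("A", n)
  stopifnot(length(resno) == n, length(ins) == n, length(aa) == n)
  dimnames(xyz) <- NULL
  structure(list(id = as.character(id), xyz = xyz,
                 resno = as.integer(resno), ins = as.character(ins),
                 aa = as.character(aa), chain = as.character(chain)),
            class = "structure3d")
}

#' @param s a `structure3d`.
#' @rdname structure3d
#' @export
nres <- function(s) nrow(s$xyz)

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d '%s': %d residues (chain %s)\n", x$id, nres(x),
              x$chain))
  invisible(x)
}

# Subset residues of a structure (keeps order of `idx`).
subset_structure <- function(s, idx) {
  structure3d(s$xyz[idx, , drop = FALSE], id = s$id, resno = s$resno[idx],
              ins = s$ins[idx], aa = s$aa[idx], chain = s$chain)
}

#' Read the C-alpha trace of one chain from a PDB file
#'
#' Parses ATOM records (via [bio3d::read.pdb()], first model only) and
#' returns one residue per `(residue number, insertion code)` with its
#' C-alpha coordinate. HETATM and non-CA atoms are ignored; for alternate
#' locations the altloc-`A` record is used when present, otherwise the
#' first listed; residues without a C-alpha are skipped.
#'
#' @param path PDB file path.
#' @param chain chain identifier to extract; `NULL` takes the first chain
#'   that has C-alpha atoms.
#' @return A [structure3d].
#' @export
read_pdb_ca <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha ATOM records in ", path)
  ca$chain[is.na(ca$chain)] <- " "
  if (is.null(chain)) {
    chain <- ca$chain[1]
  } else if (!chain %in% ca$chain) {
    stop("chain '", chain, "' not present in ", path,
         " (available: ", paste(unique(ca$chain), collapse = ", "), ")")
  }
  ca <- ca[ca$chain == chain, , drop = FALSE]
  ca$insert[is.na(ca$insert)] <- ""
  key <- paste(ca$resno, ca$insert)
  pick <- vapply(split(seq_len(nrow(ca)), factor(key, levels = unique(key))),
                 function(rows) {
                   alt <- ca$alt[rows]
                   a <- rows[!is.na(alt) & alt == "A"]
                   if (length(a)) a[1] else rows[1]
                 }, integer(1))
  ca <- ca[pick, , drop = FALSE]
  aa <- suppressWarnings(bio3d::aa321(ca$resid))
  aa[is.na(aa)] <- "X"
  base <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  structure3d(cbind(ca$x, ca$y, ca$z), id = paste0(base, trimws(chain)),
              resno = ca$resno, ins = ca$insert, aa = aa, chain = chain)
}

#' Write a C-alpha trace as PDB ATOM records
#'
#' Fixed-column ATOM records (one CA per residue, occupancy 1.00), so a
#' superposed structure can be inspected in any molecular viewer and
#' round-trips through [read_pdb_ca()] at PDB precision (3 decimals).
#'
#' @param s a [structure3d].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(s, path) {
  aa3 <- vapply(s$aa, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r) || nchar(r) != 3) "UNK" else r
  }, character(1))
  ins <- ifelse(s$ins == "", " ", substr(s$ins, 1, 1))
  ch <- substr(paste0(s$chain, " "), 1, 1)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nres(s)), aa3, ch, s$resno, ins,
    s$xyz[, 1], s$xyz[, 2], s$xyz[, 3], 1, 0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read and write reference alignments
#'
#' Reference ("gold-standard") alignments are carried in a minimal
#' whitespace-delimited two-column text format: one residue pair per line,
#' 0-based indices into the residue order of each structure, both columns
#' strictly increasing. Lines starting with `#` are comments. In memory
#' the indices are 1-based, like everything else in R.
#'
#' @param path file path.
#' @return `read_reference_alignment()` returns an [alignment] of class
#'   `c("reference_alignment", "alignment")`.
#' @export
read_reference_alignment <- function(path) {
  if (!file.exists(path)) stop("reference alignment file not found: ", path)
  raw <- trimws(readLines(path))
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (!length(raw)) {
    al <- alignment(integer(0), integer(0), scheme = "reference")
    class(al) <- c("reference_alignment", class(al))
    return(al)
  }
  fields <- strsplit(raw, "[[:space:]]+")
  if (any(lengths(fields) != 2L))
    stop("reference alignment format error: expected two columns at line ",
         which(lengths(fields) != 2L)[1])
  i <- suppressWarnings(as.integer(vapply(fields, `[`, "", 1)))
  j <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  if (anyNA(i) || anyNA(j))
    stop("reference alignment format error: non-integer index at line ",
         which(is.na(i) | is.na(j))[1])
  bad <- which(diff(i) <= 0 | diff(j) <= 0)
  if (length(bad))
    stop("reference alignment format error: indices not strictly ",
         "increasing at line ", bad[1] + 1L)
  al <- alignment(i + 1L, j + 1L, scheme = "reference")
  class(al) <- c("reference_alignment", class(al))
  al
}

#' @param al an [alignment] (1-based in memory; written 0-based).
#' @rdname read_reference_alignment
#' @export
write_reference_alignment <- function(al, path) {
  stopifnot(inherits(al, "alignment"))
  writeLines(sprintf("%d %d", al$i - 1L, al$j - 1L), path)
  invisible(path)
}

#' Read a benchmark manifest
#'
#' One structure pair per line: `pdbA chainA pdbB chainB [refalign] [tag]`,
#' where `refalign` is an optional reference-alignment file (`-` for none)
#' and `tag` an optional subset label (e.g. family/superfamily/fold).
#' Blank lines and `#` comments are ignored.
#'
#' @param path manifest file.
#' @return A data frame with columns `pdb_a`, `chain_a`, `pdb_b`,
#'   `chain_b`, `ref`, `tag`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  raw <- trimws(readLines(path))
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (!length(raw))
    return(data.frame(pdb_a = character(0), chain_a = character(0),
                      pdb_b = character(0), chain_b = character(0),
                      ref = character(0), tag = character(0)))
  fields <- strsplit(raw, "[[:space:]]+")
  if (any(lengths(fields) < 4L))
    stop("manifest format error: fewer than 4 fields at line ",
         which(lengths(fields) < 4L)[1])
  get <- function(k) vapply(fields, function(f)
    if (length(f) >= k) f[k] else NA_character_, character(1))
  ref <- get(5); ref[!is.na(ref) & ref == "-"] <- NA_character_
  data.frame(pdb_a = get(1), chain_a = get(2), pdb_b = get(3),
             chain_b = get(4), ref = ref, tag = get(6))
}
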