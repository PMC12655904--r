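#' @include AllClasses.R
NULL

WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD", "TIP")

#' Parse a receptor-ligand complex from PDB
#'
#' Reads ATOM/HETATM records through the standard PDB parser and flags the
#' ligand: by default every HETATM record that is not water; alternatively a
#' specific residue name or chain can be designated.
#'
#' @param path path to a PDB (or PDBQT; charge/type columns ignored) file.
#' @param ligandResname optional residue name identifying the ligand.
#' @param ligandChain optional chain identifier identifying the ligand.
#' @param complexId identifier; defaults to the file stem.
#' @return a [ComplexStructure-class].
#' @export
parseComplex <- function(path, ligandResname = NULL, ligandChain = NULL,
                         complexId = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  ligand <- if (!is.null(ligandResname)) a$resid == ligandResname
            else if (!is.null(ligandChain)) a$chain == ligandChain
            else a$type == "HETATM" & !(a$resid %in% WATER_RESNAMES)
  ligand[is.na(ligand)] <- FALSE
  if (!any(ligand))
    stop("no ligand atoms found (no non-water HETATM records and no ",
         "ligand selector given)")
  atoms <- data.frame(
    element = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                     substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    resname = a$resid, resno = a$resno,
    chain = ifelse(is.na(a$chain), "", a$chain),
    ligand = ligand, stringsAsFactors = FALSE)
  if (is.null(complexId))
    complexId <- sub("\\.[^.]*$", "", basename(path))
  new("ComplexStructure", complexId = complexId, atoms = atoms)
}

#' Write a complex to PDB format
#'
#' Receptor atoms as ATOM records, ligand atoms as HETATM records under
#' residue name `LIG`. Fixed-width PDB coordinate formatting; round-trips
#' through [parseComplex()].
#'
#' @param complex a [ComplexStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeComplexPdb <- function(complex, path) {
  a <- complex@atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    rec <- if (a$ligand[i]) "HETATM" else "ATOM  "
    resname <- if (a$ligand[i]) "LIG" else a$resname[i]
    chain <- if (nzchar(a$chain[i])) substr(a$chain[i], 1, 1) else " "
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, i, substr(a$element[i], 1, 1), resname, chain, a$resno[i],
            a$x[i], a$y[i], a$z[i], substr(a$element[i], 1, 2))
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Receptor residues in contact with the ligand
#'
#' A residue is a contact iff the minimum Euclidean distance over all
#' (ligand atom, residue atom) pairs is at most `cutoff` (inclusive; all
#' atoms considered, hydrogens included when present). 5 Angstrom is the
#' conventional binding-site cutoff in docking analyses.
#'
#' @param complex a [ComplexStructure-class] with at least one ligand atom.
#' @param cutoff contact distance in Angstrom, default 5.
#' @return data.frame of contact residues with columns `resno`, `resname`,
#'   `chain`, `minDist`, ordered by residue number.
#' @export
findContacts <- function(complex, cutoff = 5.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  a <- complex@atoms
  lig <- a[a$ligand, c("x", "y", "z")]
  rec <- a[!a$ligand, , drop = FALSE]
  if (!nrow(lig)) stop("complex has no ligand atoms")
  if (!nrow(rec))
    return(data.frame(resno = integer(), resname = character(),
                      chain = character(), minDist = numeric(),
                      nAtomPairs = integer(), stringsAsFactors = FALSE))
  ligM <- as.matrix(lig)
  recM <- as.matrix(rec[, c("x", "y", "z")])
  # squared distance of every receptor atom to its nearest ligand atom
  d2 <- outer(rowSums(recM^2), rowSums(ligM^2), "+") -
    2 * recM %*% t(ligM)
  minAtom <- sqrt(pmax(apply(d2, 1, min), 0))
  pairAtom <- rowSums(d2 <= cutoff^2 + 1e-12)
  key <- paste(rec$chain, rec$resno, rec$resname, sep = "|")
  minRes <- tapply(minAtom, key, min)
  pairRes <- tapply(pairAtom, key, sum)
  hit <- names(minRes)[minRes <= cutoff]
  if (!length(hit))
    return(data.frame(resno = integer(), resname = character(),
                      chain = character(), minDist = numeric(),
                      nAtomPairs = integer(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(hit, "|", fixed = TRUE))
  out <- data.frame(resno = as.integer(parts[, 2]), resname = parts[, 3],
                    chain = parts[, 1],
                    minDist = as.numeric(minRes[hit]),
                    nAtomPairs = as.integer(pairRes[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate contact frequencies across complexes
#'
#' Counts residue *instances* per 3-letter residue type by default: a
#' residue type contacted by k distinct residues summed over all complexes
#' contributes k. Alternative counting units: `"atom_pair"` counts
#' (ligand atom, residue atom) pairs within the cutoff, `"complex"` counts
#' each residue type at most once per complex. Percentages are counts over
#' the total for the chosen unit.
#'
#' @param contactSets list of [findContacts()] results (one per complex).
#' @param unit counting unit: `"instance"` (default), `"atom_pair"` or
#'   `"complex"`.
#' @return a [ContactProfile-class].
#' @examples
#' cs <- list(data.frame(resno = c(1, 2, 3), resname = c("LEU", "LEU", "PHE"),
#'                       chain = "A", minDist = 4, nAtomPairs = 1L))
#' contactPercentages(aggregateFrequencies(cs))
#' @export
aggregateFrequencies <- function(contactSets,
                                 unit = c("instance", "atom_pair",
                                          "complex")) {
  unit <- match.arg(unit)
  if (!length(contactSets)) stop("at least one complex is required")
  types <- unlist(lapply(contactSets, function(df) switch(unit,
    instance = df$resname,
    atom_pair = rep(df$resname, df$nAtomPairs),
    complex = unique(df$resname))))
  if (!length(types))
    return(new("ContactProfile", counts = integer(),
               percentages = numeric(),
               nComplexes = length(contactSets)))
  counts <- table(types)
  cnt <- setNames(as.integer(counts), names(counts))
  cnt <- sort(cnt, decreasing = TRUE)
  new("ContactProfile", counts = cnt,
      percentages = cnt / sum(cnt) * 100,
      nComplexes = length(contactSets))
}

#' Export interacting residues as FASTA
#'
#' One record per complex: the header is the complex id and the sequence the
#' one-letter codes of the contact residues in residue-number order.
#' Non-standard residues are emitted as `X`.
#'
#' @param contactsList named list of [findContacts()] results; names become
#'   FASTA headers.
#' @param path optional output file; when `NULL` the FASTA text is returned.
#' @return character vector of FASTA lines (invisibly when written to file).
#' @examples
#' exportFasta(list(cplx1 = data.frame(
#'   resno = c(346, 353, 404), resname = c("LEU", "GLU", "PHE"),
#'   chain = "A", minDist = 4)))
#' @export
exportFasta <- function(contactsList, path = NULL) {
  if (is.null(names(contactsList)) || any(!nzchar(names(contactsList))))
    stop("contactsList must be named by complex id")
  lines <- unlist(lapply(names(contactsList), function(id) {
    df <- contactsList[[id]]
    seq1 <- if (nrow(df)) {
      df <- df[order(df$resno), , drop = FALSE]
      codes <- suppressWarnings(bio3d::aa321(df$resname))
      codes[is.na(codes) | !codes %in% LETTERS] <- "X"
      paste(codes, collapse = "")
    } else ""
    c(paste0(">", id), seq1)
  }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
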