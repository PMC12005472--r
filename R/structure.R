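# Structure I/O and comparative geometry: Kabsch superposition, all-atom
# RMSD between structures, per-residue C-alpha RMSF over ensembles, box-plot
# summary statistics and atom-pair distance tables.

#' Read a PDB or mmCIF structure
#'
#' Parses via bio3d and normalizes to the package's atom table. By default
#' one alternate location per atom is kept: the highest-occupancy altloc,
#' ties broken alphabetically; `keepAltlocs = TRUE` retains all.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param keepAltlocs Keep all alternate locations.
#' @return A [Structure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif"),
                          keepAltlocs = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  a <- parsed$atom
  alt <- a$alt
  alt[is.na(alt)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  at <- data.frame(chain = ifelse(is.na(a$chain), "", a$chain),
                   resno = a$resno, resid = a$resid, atom = a$elety,
                   element = if (!is.null(a$elesy)) a$elesy else "",
                   x = a$x, y = a$y, z = a$z, occupancy = occ, altloc = alt,
                   stringsAsFactors = FALSE)
  if (!keepAltlocs && any(at$altloc != "")) {
    # highest occupancy wins; ties broken alphabetically by altloc code
    ord <- order(at$chain, at$resno, at$atom, -at$occupancy, at$altloc)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$atom)), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  rownames(at) <- NULL
  new("Structure", atoms = at, source = path)
}

#' Write a Structure as PDB
#'
#' Emits fixed-width ATOM records (coordinates to 3 decimals, occupancy to
#' 2); [readStructure()] on the output reproduces the atom table.
#'
#' @param structure A [Structure-class].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(structure, path) {
  stopifnot(is(structure, "Structure"))
  a <- structure@atoms
  nm <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
               substr(a$atom, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), nm, substr(paste0(a$altloc, " "), 1, 1), a$resid,
    a$chain, a$resno, a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build a Structure from raw coordinates
#'
#' Convenience constructor for synthetic ensembles: one pseudo-residue per
#' row, all C-alpha atoms on chain A, unless overridden.
#'
#' @param coords Numeric matrix (n x 3).
#' @param resno Residue numbers (default 1..n).
#' @param atom Atom names (default `"CA"`).
#' @param chain Chain ids (default `"A"`).
#' @param resid Residue names (default `"ALA"`).
#' @param source Label.
#' @return A [Structure-class].
#' @export
structureFromCoords <- function(coords, resno = seq_len(nrow(coords)),
                                atom = "CA", chain = "A", resid = "ALA",
                                source = "synthetic") {
  coords <- as.matrix(coords)
  new("Structure", atoms = data.frame(
    chain = rep_len(chain, nrow(coords)), resno = resno,
    resid = rep_len(resid, nrow(coords)), atom = rep_len(atom, nrow(coords)),
    element = substr(rep_len(atom, nrow(coords)), 1, 1),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occupancy = 1, altloc = "", stringsAsFactors = FALSE), source = source)
}

#' Coordinates of a structure under a selection
#'
#' @param structure A [Structure-class].
#' @param selection `"all"` or `"ca"` (C-alpha atoms).
#' @return Numeric matrix (n x 3) with pairing keys as rownames.
#' @export
structureCoords <- function(structure, selection = c("all", "ca")) {
  selection <- match.arg(selection)
  a <- structure@atoms
  if (selection == "ca") a <- a[a$atom == "CA", , drop = FALSE]
  if (nrow(a) == 0) stop("selection matched no atoms")
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$chain, a$resno, a$atom, sep = ":")
  m
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid superposition of `mobile` onto `ref` by singular-value
#' decomposition, with the determinant correction that enforces a proper
#' rotation. Inputs are paired row-by-row (equal lengths) unless a `pairing`
#' matrix of index pairs is given.
#'
#' @param ref,mobile Numeric matrices (n x 3).
#' @param pairing Optional 2-column integer matrix: rows of `ref` paired with
#'   rows of `mobile`.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   superposed mobile is `mobile %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom) and `coords` (the superposed mobile set over all its rows).
#' @export
kabschSuperpose <- function(ref, mobile, pairing = NULL) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (is.null(pairing)) {
    stopifnot(nrow(ref) == nrow(mobile))
    pairing <- cbind(seq_len(nrow(ref)), seq_len(nrow(mobile)))
  }
  A <- ref[pairing[, 1], , drop = FALSE]
  B <- mobile[pairing[, 2], , drop = FALSE]
  if (nrow(A) < 3) stop("need >= 3 paired atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- t(B0) %*% A0
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    warning("near-collinear atom set: superposition is ill-conditioned")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- ca - as.vector(R %*% cb)
  Bfit <- B %*% t(R) + matrix(tr, nrow(B), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Bfit - A)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd,
       coords = mobile %*% t(R) + matrix(tr, nrow(mobile), 3, byrow = TRUE))
}

#' RMSD without superposition
#'
#' @param a,b Paired coordinate matrices (n x 3).
#' @return Root-mean-square deviation, Angstrom.
#' @export
rawRMSD <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# pair two structures' atoms by (chain, resno, atom name); unpaired atoms
# are skipped and counted
.pair_structures <- function(sa, sb, selection = "all") {
  ka <- structureCoords(sa, selection)
  kb <- structureCoords(sb, selection)
  common <- intersect(rownames(ka), rownames(kb))
  list(a = ka[common, , drop = FALSE], b = kb[common, , drop = FALSE],
       nSkipped = (nrow(ka) - length(common)) + (nrow(kb) - length(common)))
}

#' All-atom RMSD between two structures
#'
#' Pairs atoms by (chain, residue number, atom name), skipping unpaired atoms
#' (the skip count is reported), superposes with [kabschSuperpose()] and
#' returns the paired-atom RMSD.
#'
#' @param ref,mobile [Structure-class] objects.
#' @param selection `"all"` or `"ca"`.
#' @return List with `rmsd`, `nPaired`, `nSkipped`.
#' @export
structureRMSD <- function(ref, mobile, selection = c("all", "ca")) {
  selection <- match.arg(selection)
  pr <- .pair_structures(ref, mobile, selection)
  fit <- kabschSuperpose(pr$a, pr$b)
  list(rmsd = fit$rmsd, nPaired = nrow(pr$a), nSkipped = pr$nSkipped)
}

#' Per-snapshot RMSD of an ensemble against a reference
#'
#' Each snapshot is superposed on the reference over the selection and the
#' RMSD recorded.
#'
#' @param reference A [Structure-class].
#' @param ensemble List of [Structure-class] snapshots.
#' @param selection `"all"` or `"ca"`.
#' @return Numeric vector of RMSDs, Angstrom.
#' @export
rmsdSeries <- function(reference, ensemble, selection = c("all", "ca")) {
  selection <- match.arg(selection)
  refc <- structureCoords(reference, selection)
  vapply(ensemble, function(s) {
    m <- structureCoords(s, selection)
    if (!identical(rownames(m), rownames(refc)))
      stop("inconsistent selection across snapshots")
    kabschSuperpose(refc, m)$rmsd
  }, numeric(1))
}

#' Per-residue RMSF of an ensemble
#'
#' Superposes every snapshot on the ensemble mean (the mean is re-estimated
#' and the superposition repeated twice), then reports per residue the root
#' mean square fluctuation about the mean position.
#'
#' @param ensemble List of [Structure-class] snapshots (>= 2) with matching
#'   selections.
#' @param selection `"ca"` (default) or `"all"`.
#' @return Named numeric RMSF per residue (Angstrom), names `chain:resno:atom`.
#' @export
rmsfPerResidue <- function(ensemble, selection = c("ca", "all")) {
  selection <- match.arg(selection)
  if (length(ensemble) < 2) stop("need at least 2 snapshots")
  coords <- lapply(ensemble, structureCoords, selection = selection)
  keys <- rownames(coords[[1]])
  for (m in coords)
    if (!identical(rownames(m), keys))
      stop("missing or mismatched atoms across snapshots: ",
           paste(setdiff(keys, rownames(m)), collapse = ", "))
  ref <- coords[[1]]
  for (iter in 1:2) {
    coords <- lapply(coords, function(m) kabschSuperpose(ref, m)$coords)
    ref <- Reduce(`+`, coords) / length(coords)
  }
  dev2 <- Reduce(`+`, lapply(coords, function(m) rowSums((m - ref)^2))) /
    length(coords)
  out <- sqrt(dev2)
  names(out) <- keys
  out
}

#' Box-plot summary statistics
#'
#' Quartiles by linear interpolation; whiskers extend to the most extreme
#' data points within 1.5 interquartile ranges of the box; points beyond are
#' outliers.
#'
#' @param values Numeric vector (>= 1 value).
#' @return List with `median`, `q25`, `q75`, `whiskerLo`, `whiskerHi`,
#'   `outliers`.
#' @examples
#' boxStats(c(1, 2, 3, 4, 100))$outliers  # 100
#' @export
boxStats <- function(values) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  list(median = q[2], q25 = q[1], q75 = q[3],
       whiskerLo = min(values[inside]), whiskerHi = max(values[inside]),
       outliers = sort(values[!inside]))
}

# resolve an atom selector "chain:resno:atom" (chain may be empty) to one row
.resolve_selector <- function(structure, sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("selector must be 'chain:resno:atomname': ", sel)
  a <- structure@atoms
  hit <- which((parts[1] == "" | a$chain == parts[1]) &
                 a$resno == as.integer(parts[2]) & a$atom == parts[3])
  if (length(hit) == 0) stop("selector matched no atom: ", sel)
  if (length(hit) > 1)
    stop("ambiguous selector ", sel, ": matches rows ",
         paste(hit, collapse = ", "))
  hit
}

#' Distances between selected atom pairs
#'
#' @param structure A [Structure-class].
#' @param pairs List of length-2 character vectors, each an atom selector
#'   `"chain:resno:atomname"` (empty chain matches any chain).
#' @param digits Decimals for the reported distance (default 1, as in
#'   typical active-site figures); `NULL` for full precision.
#' @return data.frame with columns `from`, `to`, `distance` (Angstrom).
#' @export
distanceTable <- function(structure, pairs, digits = 1) {
  a <- structure@atoms
  rows <- lapply(pairs, function(p) {
    i <- .resolve_selector(structure, p[1])
    j <- .resolve_selector(structure, p[2])
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
    data.frame(from = p[1], to = p[2],
               distance = if (is.null(digits)) d else round(d, digits))
  })
  do.call(rbind, rows)
}
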