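# Plain-text serialization: CSV for injection series, buffer series, lambda
# trajectories and titration curves; PQR plus a JSON sidecar for titratable
# systems.

#' Write / read an injection series as CSV
#'
#' The CSV carries columns `volume` (uL) and `heat` (kJ/mol of injectant);
#' the cell setup travels in `#key=value` comment lines before the header.
#'
#' @param series An [InjectionSeries-class].
#' @param path Output file.
#' @return `writeInjectionSeries` returns `path` invisibly;
#'   `readInjectionSeries` returns an [InjectionSeries-class].
#' @export
writeInjectionSeries <- function(series, path) {
  stopifnot(is(series, "InjectionSeries"))
  meta <- sprintf("#%s=%.10g",
                  c("cellConc", "syringeConc", "cellVolume", "temperature"),
                  c(series@cellConc, series@syringeConc, series@cellVolume,
                    series@temperature))
  writeLines(meta, path)
  suppressWarnings(utils::write.table(series@injections, path, sep = ",",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' @rdname writeInjectionSeries
#' @export
readInjectionSeries <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", metaLines), "=", fixed = TRUE)
  meta <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          vapply(kv, `[`, "", 1))
  inj <- utils::read.csv(text = lines[!grepl("^#", lines)])
  injectionSeries(inj$volume, inj$heat, meta[["cellConc"]],
                  meta[["syringeConc"]], meta[["cellVolume"]],
                  meta[["temperature"]])
}

#' Write / read a buffer series as CSV
#'
#' Columns `buffer`, `dHIonization`, `dHObserved` (kJ/mol), plus any extra
#' columns present (e.g. `Kd`, `N`).
#'
#' @param points data.frame as produced by [genBufferSeries()].
#' @param path Output file.
#' @export
writeBufferSeries <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBufferSeries
#' @export
readBufferSeries <- function(path) {
  pts <- utils::read.csv(path)
  stopifnot(all(c("dHIonization", "dHObserved") %in% names(pts)))
  pts
}

#' Write / read lambda trajectories as per-(site, replica) CSV files
#'
#' One file `lambda_<site>_rep<r>.csv` per site and replica with columns
#' `pH_index`, `frame`, `lambda`, plus a `lambda_meta.json` sidecar holding
#' the pH grid, site names and burn-in.
#'
#' @param trajs A [LambdaTrajectorySet-class].
#' @param dir Output directory (created if missing).
#' @export
writeLambdaTrajectories <- function(trajs, dir) {
  stopifnot(is(trajs, "LambdaTrajectorySet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(trajs@sites)) {
    for (r in seq_along(trajs@lambda[[i]])) {
      m <- trajs@lambda[[i]][[r]]
      df <- data.frame(pH_index = rep(seq_len(ncol(m)), each = nrow(m)),
                       frame = rep(seq_len(nrow(m)), ncol(m)),
                       lambda = as.vector(m))
      utils::write.csv(df, file.path(dir, sprintf("lambda_%s_rep%d.csv",
                                                  trajs@sites[i], r)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  jsonlite::write_json(list(sites = trajs@sites, pH = trajs@pH,
                            burnIn = trajs@burnIn,
                            nReplicas = length(trajs@lambda[[1]])),
                       file.path(dir, "lambda_meta.json"), digits = NA)
  invisible(dir)
}

#' @rdname writeLambdaTrajectories
#' @export
readLambdaTrajectories <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "lambda_meta.json"),
                              simplifyVector = TRUE)
  lam <- lapply(meta$sites, function(s) {
    lapply(seq_len(meta$nReplicas), function(r) {
      df <- utils::read.csv(file.path(dir, sprintf("lambda_%s_rep%d.csv",
                                                   s, r)))
      matrix(df$lambda, ncol = length(meta$pH))
    })
  })
  names(lam) <- meta$sites
  new("LambdaTrajectorySet", sites = meta$sites, pH = meta$pH,
      burnIn = as.integer(meta$burnIn), lambda = lam)
}

#' Write / read a titratable system as PQR plus a JSON sidecar
#'
#' The PQR carries positions, background charges and radii (whitespace
#' separated); site metadata (classes, reference pKas, charge sets, acid and
#' ligand flags) travels in `<path>.sites.json`.
#'
#' @param system A [TitratableSiteSystem-class].
#' @param path Output PQR path.
#' @export
writeToySystem <- function(system, path) {
  stopifnot(is(system, "TitratableSiteSystem"))
  a <- system@atoms
  lines <- sprintf(
    "ATOM  %5d  X   UNK A%4d    %8.3f%8.3f%8.3f %7.4f %6.3f",
    seq_len(nrow(a)), seq_len(nrow(a)), a$x, a$y, a$z, a$charge, a$radius)
  writeLines(lines, path)
  jsonlite::write_json(
    list(ligandAtoms = which(a$ligand), sites = system@sites),
    paste0(path, ".sites.json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeToySystem
#' @export
readToySystem <- function(path) {
  pqr <- readPQR(path)
  meta <- jsonlite::read_json(paste0(path, ".sites.json"),
                              simplifyVector = TRUE)
  lig <- rep(FALSE, nrow(pqr))
  lig[unlist(meta$ligandAtoms)] <- TRUE
  pqr$ligand <- lig
  st <- unname(apply(meta$sites, 1, as.list))
  st <- lapply(st, function(s) {
    s$atomIdx <- as.integer(unlist(s$atomIdx))
    s$qProt <- as.numeric(unlist(s$qProt))
    s$qDeprot <- as.numeric(unlist(s$qDeprot))
    s$acid <- as.logical(s$acid)
    s$ligand <- as.logical(s$ligand)
    s$pkaRef <- as.numeric(s$pkaRef)
    s
  })
  new("TitratableSiteSystem", atoms = pqr, sites = st)
}

#' Read a PQR file into an atom table
#'
#' Whitespace-separated PQR (position, charge, radius) via bio3d.
#'
#' @param path PQR file path.
#' @return data.frame with columns `x`, `y`, `z`, `radius`, `charge`.
#' @export
readPQR <- function(path) {
  p <- bio3d::read.pqr(path)
  data.frame(x = p$atom$x, y = p$atom$y, z = p$atom$z,
             radius = as.numeric(p$atom$b), charge = as.numeric(p$atom$o))
}

#' Write / read a titration curve
#'
#' CSV columns: `pH`, one protonated-fraction and one SE column per site,
#' `nBound`. The JSON summary written alongside (`<path>.json`) holds the
#' per-site half-protonation points.
#'
#' @param curve A [TitrationCurve-class].
#' @param path Output CSV path.
#' @param json Also write the JSON summary.
#' @export
writeTitrationCurve <- function(curve, path, json = TRUE) {
  stopifnot(is(curve, "TitrationCurve"))
  df <- data.frame(pH = curve@pH, curve@theta, curve@mcSE, curve@nBound)
  names(df) <- c("pH", paste0("theta_", curve@siteIds),
                 paste0("se_", curve@siteIds), "nBound")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (json)
    jsonlite::write_json(as.list(pKaHalf(curve)), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTitrationCurve
#' @export
readTitrationCurve <- function(path) {
  df <- utils::read.csv(path)
  th <- as.matrix(df[, grep("^theta_", names(df)), drop = FALSE])
  se <- as.matrix(df[, grep("^se_", names(df)), drop = FALSE])
  ids <- sub("^theta_", "", colnames(th))
  dimnames(th) <- dimnames(se) <- NULL
  new("TitrationCurve", pH = df$pH, theta = th, nBound = df$nBound,
      mcSE = se, siteIds = ids)
}
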