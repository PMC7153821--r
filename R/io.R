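# Plain-text serialization: torsion CSVs, reference tables, specs and
# reports as JSON.

#' Write / read a torsion trajectory as CSV
#'
#' One row per frame, header `phi_1,psi_1,...`; metadata (frame_dt, loop_id)
#' travels in a leading comment line.
#'
#' @param traj a [torsion_trajectory()].
#' @param path output file.
#' @export
write_torsion_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# loop_id=%s frame_dt_ns=%.12g", traj$loop_id, traj$frame_dt), con)
  utils::write.csv(as.data.frame(traj$angles), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_torsion_csv
#' @return for the reader, a [torsion_trajectory()].
#' @export
read_torsion_csv <- function(path) {
  first <- readLines(path, n = 1)
  frame_dt <- 1; loop_id <- basename(path)
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    m <- regmatches(first, regexec("loop_id=(\\S+) frame_dt_ns=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 3) { loop_id <- m[2]; frame_dt <- as.numeric(m[3]) }
  }
  ang <- as.matrix(utils::read.csv(path, skip = skip, check.names = FALSE))
  torsion_trajectory(ang, colnames(ang), frame_dt = frame_dt, loop_id = loop_id)
}

#' Write / read reference conformations as CSV
#'
#' Columns: name, then the 2L angle columns (phi_1, psi_1, ...).
#'
#' @param refs list of [reference_conformation()] objects.
#' @param path file path.
#' @export
write_references_csv <- function(refs, path) {
  tab <- do.call(rbind, lapply(refs, function(r) {
    d <- as.data.frame(t(r$torsions))
    names(d) <- phi_psi_names(length(r$torsions) / 2)
    cbind(data.frame(name = r$name), d)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_references_csv
#' @return for the reader, a named list of [reference_conformation()].
#' @export
read_references_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  refs <- lapply(seq_len(nrow(tab)), function(i) {
    reference_conformation(tab$name[i], as.numeric(tab[i, -1]), source = path)
  })
  names(refs) <- tab$name
  refs
}

#' Write a synthetic spec (or any plain list) as JSON
#' @param x list-like object.
#' @param path file path.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
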