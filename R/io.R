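# File formats: a versioned JSON schema for spin systems, and CSV decay
# traces with '#'-prefixed metadata header lines.

.SPINSYS_SCHEMA <- "spindec-spin-system/1"

#' Write a spin system to a JSON file
#'
#' Schema (version `spindec-spin-system/1`): top-level fields `schema`,
#' `protons` (list of `{id, xyz_angstrom, tensor_MHz}` with a 3x3 tensor),
#' `methyls` (list of `{ids, tunnel_kHz}`) and `electron`
#' (`{xyz_angstrom, offset_sigma_MHz}`).
#'
#' @param system A [spin_system()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spin_system <- function(system, path) {
  stopifnot(inherits(system, "spin_system"))
  obj <- list(
    schema = .SPINSYS_SCHEMA,
    protons = lapply(system$protons, function(p)
      list(id = p$id, xyz_angstrom = p$position,
           tensor_MHz = unclass(p$tensor))),
    methyls = lapply(system$methyls, function(m)
      list(ids = m$proton_ids, tunnel_kHz = m$tunnel_kHz)),
    electron = list(xyz_angstrom = system$electron_position,
                    offset_sigma_MHz = system$offset_sigma))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a spin system from a JSON file
#'
#' @param path File written by [write_spin_system()].
#' @return A [spin_system()].
#' @export
read_spin_system <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(obj$schema, .SPINSYS_SCHEMA))
    stop(sprintf("unsupported spin-system schema: %s",
                 if (is.null(obj$schema)) "<missing>" else obj$schema))
  protons <- lapply(obj$protons, function(p)
    proton(p$id, p$xyz_angstrom, hyperfine_tensor(p$tensor_MHz)))
  methyls <- lapply(obj$methyls, function(m)
    methyl_group(m$ids, m$tunnel_kHz))
  spin_system(protons, methyls,
              electron_position = obj$electron$xyz_angstrom,
              offset_sigma = obj$electron$offset_sigma_MHz)
}

#' Write a decay trace to CSV
#'
#' Columns `T_us, signal`, preceded by `#`-prefixed metadata lines
#' (key: value).
#'
#' @param trace A `cluster_trace` (or `expansion_result`).
#' @param path Output file path.
#' @param meta Named list of metadata entries for the header.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, meta = list()) {
  if (inherits(trace, "expansion_result")) {
    meta <- c(list(engine = trace$engine,
                   order = paste(trace$order, collapse = ",")), meta)
    trace <- trace$trace
  }
  stopifnot(inherits(trace, "cluster_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(format = "spindec-trace/1", mode = trace$mode), meta)
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(data.frame(T_us = trace$times, signal = trace$values),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a decay trace from CSV
#'
#' @param path File written by [write_trace_csv()].
#' @return A `cluster_trace` with the metadata as attribute `meta`.
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = lines[setdiff(seq_along(lines), hdr)])
  mode <- if (identical(meta$mode, "dressed")) "dressed" else "bare"
  out <- .new_cluster_trace(df$T_us, df$signal, NA_real_, mode)
  attr(out, "meta") <- meta
  out
}

#' Export fixture coordinates as XYZ
#'
#' Plain XYZ with the electron as a pseudo-atom `X` and protons as `H`,
#' for quick visualization of synthetic geometries.
#'
#' @param system A [spin_system()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(system, path) {
  stopifnot(inherits(system, "spin_system"))
  n <- length(system$protons)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(n + 1), "spindec synthetic spin system"), con)
  writeLines(sprintf("X %12.6f %12.6f %12.6f",
                     system$electron_position[1], system$electron_position[2],
                     system$electron_position[3]), con)
  for (p in system$protons)
    writeLines(sprintf("H %12.6f %12.6f %12.6f",
                       p$position[1], p$position[2], p$position[3]), con)
  invisible(path)
}
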