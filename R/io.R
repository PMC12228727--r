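#' Read an optical-property spectrum from CSV
#'
#' Expected header: `wavelength_nm,mu_a_per_mm,mu_s_prime_per_mm[,g,n]`.
#' Rows are sorted by wavelength (with a warning if the file was out of
#' order); duplicate wavelengths and negative coefficients are rejected
#' with messages naming the offending column or row.
#'
#' @param path CSV file path
#' @return spectrum data frame with internal column names `wavelength_nm`,
#'   `mu_a`, `mu_s_prime`, `g`, `n`
#' @export
read_spectrum_csv <- function(path) {
  x <- read.csv(path)
  need <- c("wavelength_nm", "mu_a_per_mm", "mu_s_prime_per_mm")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in need) {
    bad <- which(!is.finite(x[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric value in '%s' at row %d",
                   basename(path), col, bad[1]), call. = FALSE)
  }
  bad <- which(x$mu_a_per_mm < 0 | x$mu_s_prime_per_mm < 0)
  if (length(bad))
    stop(sprintf("%s: negative coefficient at row %d", basename(path), bad[1]),
         call. = FALSE)
  if (anyDuplicated(x$wavelength_nm))
    stop(sprintf("%s: duplicate wavelength %g nm", basename(path),
                 x$wavelength_nm[duplicated(x$wavelength_nm)][1]), call. = FALSE)
  if (is.unsorted(x$wavelength_nm)) {
    warning(sprintf("%s: wavelengths out of order; sorting", basename(path)),
            call. = FALSE)
    x <- x[order(x$wavelength_nm), , drop = FALSE]
  }
  out <- data.frame(wavelength_nm = x$wavelength_nm, mu_a = x$mu_a_per_mm,
                    mu_s_prime = x$mu_s_prime_per_mm,
                    g = if (is.null(x$g)) 0 else x$g,
                    n = if (is.null(x$n)) NA_real_ else x$n)
  rownames(out) <- NULL
  out
}

#' Write an optical-property spectrum to CSV
#'
#' Inverse of [read_spectrum_csv()]; numbers are written at full double
#' precision so a read/write roundtrip is lossless well beyond 12
#' significant digits.
#'
#' @param spectrum spectrum data frame (internal column names)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectrum_csv <- function(spectrum, path) {
  sp <- as_spectrum(spectrum)
  out <- data.frame(wavelength_nm = sp$wavelength_nm,
                    mu_a_per_mm = sp$mu_a, mu_s_prime_per_mm = sp$mu_s_prime,
                    g = sp$g, n = sp$n)
  write_atomic_csv(out, path)
}

#' Read thin-section reflectance/transmittance measurements from CSV
#'
#' Expected header: `wavelength_nm,R_total,T_total,thickness_mm,n_sample`
#' with an optional `replicate` column (one file per section is the
#' conventional layout, in which case set `replicate` on return).
#'
#' @param path CSV file path
#' @param replicate optional replicate id to stamp on all rows
#' @return measurement data frame as consumed by [imc_fit()]
#' @export
read_rt_csv <- function(path, replicate = NULL) {
  x <- read.csv(path)
  need <- c("wavelength_nm", "R_total", "T_total")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(x$R_total < 0 | x$T_total < 0 | x$R_total + x$T_total > 1)
  if (length(bad))
    stop(sprintf("%s: infeasible R/T at row %d", basename(path), bad[1]),
         call. = FALSE)
  if (!is.null(replicate)) x$replicate <- replicate
  x[order(x$wavelength_nm), , drop = FALSE]
}

# atomic CSV write: write to a sibling temp file, then rename
write_atomic_csv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Export a transport result as JSON
#'
#' @param result a `transport_result`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_transport_json <- function(result, path) {
  stopifnot(inherits(result, "transport_result"))
  obj <- list(wavelength_nm = result$wavelength,
              R_specular = result$R_specular, R_diffuse = result$R_diffuse,
              T_total = result$T_total, A_total = result$A_total,
              se = result$se,
              fluence = list(dz_mm = result$dz,
                             values = if (is.null(result$fluence)) numeric(0)
                                      else result$fluence$phi))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a penetration sweep as CSV
#'
#' @param sweep a `penetration_sweep` from [wavelength_sweep()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sweep_csv <- function(sweep, path) {
  write_atomic_csv(as.data.frame(sweep), path)
}

#' Build a run manifest
#'
#' Records what went into a pipeline run: an MD5 digest of the
#' configuration, the seeds, package and R versions, digests of the input
#' files, and a timestamp.  Outputs written under the same manifest inputs
#' reproduce bit-identically (the manifest itself carries the timestamp).
#'
#' @param config configuration list
#' @param seeds named list/vector of seeds used
#' @param inputs character vector of input file paths to digest
#' @return list of class `run_manifest`
#' @export
run_manifest <- function(config, seeds, inputs = character()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # canonical serialization of the config for hashing
  canon <- if (length(config) && !is.null(names(config)))
    config[order(names(config))] else config
  writeLines(deparse(canon), tmp)
  structure(list(
    config_hash = unname(tools::md5sum(tmp)),
    seeds = as.list(seeds),
    package_version = as.character(packageVersion("corneauv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input_digests = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a result bundle to a directory
#'
#' Writes every recognised component of `bundle` (spectra, coefficient
#' tables, sweeps, plain data frames) as CSV plus a `manifest.json`; all
#' writes are atomic.  An empty bundle yields the manifest only.
#'
#' @param bundle named list of results
#' @param out_dir output directory (created if needed)
#' @param manifest a [run_manifest()]; a minimal one is built if omitted
#' @return character vector of files written, invisibly
#' @export
write_results <- function(bundle, out_dir, manifest = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  written <- character()
  for (nm in names(bundle)) {
    x <- bundle[[nm]]
    path <- file.path(out_dir, paste0(nm, ".csv"))
    if (inherits(x, "penetration_sweep")) write_sweep_csv(x, path)
    else if (inherits(x, "transport_result")) {
      path <- file.path(out_dir, paste0(nm, ".json"))
      write_transport_json(x, path)
    } else if (is.data.frame(x)) write_atomic_csv(x, path)
    else next
    written <- c(written, path)
  }
  if (is.null(manifest)) manifest <- run_manifest(list(), list(), character())
  mpath <- file.path(out_dir, "manifest.json")
  tmp <- tempfile(tmpdir = out_dir, fileext = ".tmp")
  jsonlite::write_json(unclass(manifest), tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, mpath)
  invisible(c(written, mpath))
}
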