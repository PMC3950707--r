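#' Write a cohort of traces to delimited text plus a JSON manifest
#'
#' One tab-delimited file per molecule (`time_s` then `cy3`, or `time_s`,
#' `donor`, `acceptor`), values printed with 17 significant digits so a
#' write/read round trip is bit-exact, plus a `manifest.json` recording the
#' schema version, modality, frame time, per-trace concentration and file,
#' and (for synthetic cohorts) the generator configuration.
#'
#' @param traces List of [sm_trace] objects (e.g. from
#'   [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @param manifest_name Manifest file name (default `"manifest.json"`).
#' @return Invisibly, the manifest path.
#' @export
write_traces <- function(traces, dir, manifest_name = "manifest.json") {
  if (length(traces) == 0L) stop("no traces to write", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  modality <- unique(vapply(traces, function(tr) tr$modality, ""))
  dt <- unique(vapply(traces, function(tr) tr$dt, 1))
  if (length(modality) != 1L || length(dt) != 1L)
    stop("a cohort must share one modality and frame time", call. = FALSE)

  fmt <- function(x) sprintf("%.17g", x)
  entries <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    n <- length(tr$channels[[1L]])
    time_s <- (seq_len(n) - 1L) * tr$dt
    cols <- c(list(time_s = fmt(time_s)), lapply(tr$channels, fmt))
    fname <- paste0(tr$molecule_id, ".tsv")
    path <- file.path(dir, fname)
    writeLines(c(paste(names(cols), collapse = "\t"),
                 do.call(paste, c(unname(cols), sep = "\t"))), path)
    entries[[i]] <- list(molecule_id = tr$molecule_id, file = fname,
                         concentration_nM = tr$tf_concentration,
                         colocalized_acceptor = tr$colocalized_acceptor)
  }
  manifest <- list(schema_version = "1.0", modality = modality, dt = dt,
                   traces = entries)
  cfg <- attr(traces, "config")
  if (!is.null(cfg)) manifest$ground_truth <- unclass(cfg)
  mf <- attr(traces, "manifest")
  if (!is.null(mf)) manifest$seeds <- as.list(setNames(mf$seed, mf$molecule_id))
  mpath <- file.path(dir, manifest_name)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a cohort of traces from a JSON manifest
#'
#' @param manifest_path Path to a manifest written by [write_traces()].
#' @return A list of [sm_trace] objects (class `sm_cohort`) with the
#'   manifest attached as an attribute.
#' @export
read_traces <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  modality <- manifest$modality
  dt <- manifest$dt
  traces <- vector("list", length(manifest$traces))
  for (i in seq_along(manifest$traces)) {
    e <- manifest$traces[[i]]
    path <- file.path(dir, e$file)
    if (!file.exists(path))
      stop("trace file referenced by manifest is missing: ", path,
           call. = FALSE)
    tab <- tryCatch(
      utils::read.delim(path, colClasses = "numeric", check.names = FALSE),
      warning = function(w) stop("malformed trace file ", path, ": ",
                                 conditionMessage(w), call. = FALSE),
      error = function(err) stop("malformed trace file ", path, ": ",
                                 conditionMessage(err), call. = FALSE))
    nf <- utils::count.fields(path, sep = "\t")
    if (length(unique(nf)) != 1L)
      stop("ragged columns in trace file ", path, " (line ",
           which(nf != nf[1L])[1L], ")", call. = FALSE)
    if (!"time_s" %in% names(tab))
      stop("trace file ", path, " lacks a time_s column", call. = FALSE)
    if (is.unsorted(tab$time_s, strictly = TRUE))
      stop("non-monotone time column in ", path, call. = FALSE)
    channels <- as.list(tab[setdiff(names(tab), "time_s")])
    traces[[i]] <- sm_trace(channels, dt = dt, modality = modality,
                            tf_concentration = as.numeric(e$concentration_nM),
                            molecule_id = e$molecule_id,
                            colocalized_acceptor =
                              isTRUE(e$colocalized_acceptor))
  }
  structure(traces, manifest = manifest, class = c("sm_cohort", "list"))
}

#' Read a pipeline configuration file (JSON or YAML)
#'
#' @param path Configuration file; `.yaml`/`.yml` needs the `yaml` package,
#'   anything else is parsed as JSON.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the `yaml` package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
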