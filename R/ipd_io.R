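#' Read individual participant survival data
#'
#' Reads a delimited text file with header columns `trial`, `treatment`,
#' `time`, `event` (extra columns are kept), validates it against a network
#' specification, and returns a validated IPD dataset. Row order is preserved.
#'
#' Times are accepted in any single unit; all modelling is on ln(time) and
#' nothing is rescaled, so knot locations are unit-dependent.
#'
#' @param path path to a CSV/TSV file (delimiter auto-detected from the
#'   extension; comma by default).
#' @param network an [network_spec()] object.
#' @return a `data.frame` of class `rp_ipd` with columns `trial`, `treatment`,
#'   `time`, `event` (and `patient` if present), the network attached as
#'   attribute `network`.
#' @export
read_ipd <- function(path, network) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  ipd_data(df, network)
}

#' Construct / validate an IPD dataset from a data frame
#'
#' @param df data frame with columns `trial`, `treatment`, `time`, `event`.
#' @param network an [network_spec()] object.
#' @return validated `rp_ipd` data frame.
#' @export
ipd_data <- function(df, network) {
  need <- c("trial", "treatment", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df$trial <- as.character(df$trial)
  df$treatment <- as.character(df$treatment)
  df$time <- as.numeric(df$time)
  df$event <- as.numeric(df$event)

  bad <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad))
    stop("non-positive time at row ", bad[1], " (time = ", df$time[bad[1]],
         "); ln(time) must be defined", call. = FALSE)
  bad <- which(!df$event %in% c(0, 1))
  if (length(bad))
    stop("event indicator outside {0,1} at row ", bad[1], call. = FALSE)
  bad <- which(!df$treatment %in% network$treatments)
  if (length(bad))
    stop("treatment '", df$treatment[bad[1]], "' at row ", bad[1],
         " is absent from the network", call. = FALSE)

  for (tid in unique(df$trial)) {
    rows <- df[df$trial == tid, ]
    trts <- unique(rows$treatment)
    if (length(trts) < 2)
      stop("trial '", tid, "' has fewer than 2 distinct treatments",
           call. = FALSE)
    if (!any(rows$event == 1))
      stop("trial '", tid, "' has no uncensored event", call. = FALSE)
    match_design(network, trts)  # errors if not a declared design
  }
  structure(df, class = c("rp_ipd", "data.frame"), network = network)
}

#' Write an IPD dataset back to CSV
#'
#' Round-trips exactly with [read_ipd()]: records and field values preserved.
#'
#' @param data an `rp_ipd` data frame.
#' @param path output file path.
#' @export
write_ipd <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Split a treatment by a trial-level flag
#'
#' Rewrites the treatment label of the split treatment to its augmented label
#' in every trial whose flag matches a declared split rule, leaving all other
#' rows untouched. Used, e.g., to treat the same regimen delivered with short
#' vs long chemotherapy cycles as two distinct network treatments.
#'
#' @param data an `rp_ipd` data frame whose attached network declares the
#'   split rules (see [network_spec()]).
#' @param network the network (defaults to the one attached to `data`).
#' @param flags named character vector or list, `trial id -> flag value`.
#' @return the relabelled, revalidated `rp_ipd` (same number of records).
#' @export
apply_splits <- function(data, network = attr(data, "network"), flags) {
  if (length(flags) == 0) return(data)
  df <- as.data.frame(data)
  unknown <- setdiff(names(flags), unique(df$trial))
  if (length(unknown))
    stop("flag references unknown trial '", unknown[1], "'", call. = FALSE)
  for (tid in names(flags)) {
    hit <- FALSE
    for (sp in network$splits) {
      if (!identical(as.character(flags[[tid]]), as.character(sp$flag))) next
      sel <- df$trial == tid & df$treatment == sp$treatment
      if (!any(sel))
        stop("trial '", tid, "' is flagged for splitting but contains no '",
             sp$treatment, "' arm", call. = FALSE)
      df$treatment[sel] <- sp$label
      hit <- TRUE
    }
    if (!hit)
      stop("flag value '", flags[[tid]], "' for trial '", tid,
           "' matches no declared split", call. = FALSE)
  }
  ipd_data(df, network)
}

#' @export
print.rp_ipd <- function(x, ...) {
  cat("IPD survival dataset:", nrow(x), "patients,",
      length(unique(x$trial)), "trials,",
      length(unique(x$treatment)), "treatments;",
      sum(x$event == 1), "events\n")
  NextMethod()
}

#' Read a network / run configuration file
#'
#' YAML with top-level keys `network` (treatments, reference, designs, loops,
#' splits, basic_contrasts), and optionally `knots`, `priors`, `mcmc` and
#' `model` sections used by the command-line front end.
#'
#' @param path YAML file path.
#' @return list with elements `network` (an `rp_network`) and the raw
#'   `knots`, `priors`, `mcmc`, `model` sections (possibly NULL).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$network))
    stop("config has no 'network' section", call. = FALSE)
  nw <- cfg$network
  net <- network_spec(
    treatments = unlist(nw$treatments),
    reference = if (is.null(nw$reference)) unlist(nw$treatments)[1]
                else nw$reference,
    designs = nw$designs %||% stop("network config needs 'designs'",
                                   call. = FALSE),
    basic_contrasts = nw$basic_contrasts,
    loops = nw$loops %||% list(),
    splits = nw$splits %||% list())
  list(network = net, knots = cfg$knots, priors = cfg$priors,
       mcmc = cfg$mcmc, model = cfg$model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
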