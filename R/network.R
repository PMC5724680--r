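#' Declare a treatment network
#'
#' A network specification names the treatments, the reference treatment, the
#' trial designs (the sets of treatments compared within a trial, each with its
#' own design reference), the basic contrasts parameterising the network, any
#' treatment loops eligible for an inconsistency parameter, and any
#' treatment-splitting rules driven by a trial-level flag.
#'
#' The basic contrasts are the q independent comparisons (q = number of
#' treatments minus one) in which every other comparison is expressed through
#' the consistency equations. By default they are reference vs each
#' non-reference treatment, in treatment order. Treatment-contrast variables
#' for any design arm then take values in \{-1, 0, 1\}.
#'
#' Splits are declared on the final (post-split) network: `treatments` and
#' `designs` must already contain the augmented labels, and each split rule
#' records which original treatment label, under which trial-level flag value,
#' is rewritten to which augmented label by [apply_splits()].
#'
#' @param treatments character vector of treatment labels (post-split universe).
#' @param reference the network reference treatment; default first element.
#' @param designs list; each element a character vector of treatment labels or
#'   a list with elements `treatments` and `reference`. If no design reference
#'   is given, the network reference is used when present, otherwise the first
#'   listed treatment.
#' @param basic_contrasts optional list of length-2 character vectors
#'   `c(from, to)`; default `reference` vs each other treatment.
#' @param loops list of length-3 character vectors `c(apex, b, c)`: the loop is
#'   closed by a two-arm design \{b, c\}, with indirect evidence flowing
#'   through `apex`.
#' @param splits list of lists with elements `treatment`, `flag`, `label`.
#' @return an object of class `rp_network`.
#' @seealso [build_contrasts()], [apply_splits()]
#' @export
network_spec <- function(treatments, reference = treatments[1], designs,
                         basic_contrasts = NULL, loops = list(),
                         splits = list()) {
  treatments <- as.character(treatments)
  if (anyDuplicated(treatments))
    stop("duplicate treatment labels in network", call. = FALSE)
  if (!reference %in% treatments)
    stop("reference treatment '", reference, "' not among treatments",
         call. = FALSE)

  designs <- lapply(designs, function(d) {
    if (is.character(d)) d <- list(treatments = d)
    d$treatments <- as.character(d$treatments)
    if (length(d$treatments) < 2)
      stop("every design needs >= 2 treatments", call. = FALSE)
    if (!all(d$treatments %in% treatments))
      stop("design uses treatment(s) not in the network: ",
           paste(setdiff(d$treatments, treatments), collapse = ", "),
           call. = FALSE)
    if (is.null(d$reference))
      d$reference <- if (reference %in% d$treatments) reference
                     else d$treatments[1]
    if (!d$reference %in% d$treatments)
      stop("design reference not in design", call. = FALSE)
    d
  })

  if (is.null(basic_contrasts)) {
    basic_contrasts <- lapply(setdiff(treatments, reference),
                              function(tr) c(reference, tr))
  }
  q <- length(treatments) - 1L
  if (length(basic_contrasts) != q)
    stop("need exactly ", q, " basic contrasts for ", q + 1L, " treatments",
         call. = FALSE)
  for (bc in basic_contrasts)
    if (length(bc) != 2 || !all(bc %in% treatments))
      stop("malformed basic contrast", call. = FALSE)

  net <- structure(
    list(treatments = treatments, reference = reference, designs = designs,
         basic_contrasts = basic_contrasts, loops = loops, splits = splits),
    class = "rp_network")

  # every design must be expressible in the basic contrasts
  for (d in designs)
    for (arm in setdiff(d$treatments, d$reference))
      build_contrasts(net, d$treatments, arm)

  for (lp in loops) {
    if (length(lp) != 3 || !all(lp %in% treatments))
      stop("loop must name three network treatments", call. = FALSE)
    loop_closing_design(net, lp)  # errors if absent / malformed
  }
  closers <- vapply(loops, function(lp) paste(sort(lp[2:3]), collapse = "|"),
                    "")
  if (anyDuplicated(closers))
    stop("loops must be edge-disjoint (each closing design in one loop only)",
         call. = FALSE)

  for (sp in splits) {
    if (!all(c("treatment", "flag", "label") %in% names(sp)))
      stop("each split needs treatment, flag and label", call. = FALSE)
    if (!sp$label %in% treatments)
      stop("split label '", sp$label, "' must be a declared treatment",
           call. = FALSE)
  }
  net
}

#' @export
print.rp_network <- function(x, ...) {
  cat("Treatment network:", length(x$treatments), "treatments,",
      length(x$designs), "designs\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "),
      "(reference:", paste0(x$reference, ")\n"))
  for (d in x$designs)
    cat("  design:", paste(d$treatments, collapse = " vs "),
        "(ref", paste0(d$reference, ")\n"))
  if (length(x$loops))
    for (lp in x$loops)
      cat("  loop:", paste(lp, collapse = "-"), "\n")
  invisible(x)
}

n_basic <- function(network) length(network$basic_contrasts)

basic_labels <- function(network)
  vapply(network$basic_contrasts, function(bc) paste(bc, collapse = ":"), "")

#' Treatment-contrast vector for one trial arm
#'
#' Expresses the effect of an assigned treatment relative to its design
#' reference in the basic contrasts via the consistency equations. Patients on
#' the design reference arm get the zero vector; other arms get a vector of
#' -1/0/1 coefficients.
#'
#' @param network an `rp_network`.
#' @param design character vector of the trial's treatments (must match a
#'   declared design).
#' @param assigned the arm's treatment label.
#' @return numeric vector of length q with entries in \{-1, 0, 1\}.
#' @export
build_contrasts <- function(network, design, assigned) {
  d <- match_design(network, design)
  if (!assigned %in% d$treatments)
    stop("assigned treatment '", assigned, "' not in design", call. = FALSE)
  if (assigned == d$reference)
    return(numeric(n_basic(network)))
  trts <- network$treatments
  # columns of M: each basic contrast (a, b) is e_b - e_a in effect space
  M <- vapply(network$basic_contrasts, function(bc) {
    v <- numeric(length(trts))
    v[match(bc[2], trts)] <- 1
    v[match(bc[1], trts)] <- -1
    v
  }, numeric(length(trts)))
  target <- numeric(length(trts))
  target[match(assigned, trts)] <- 1
  target[match(d$reference, trts)] <- -1
  x <- qr.solve(M, target, tol = 1e-10)
  if (max(abs(M %*% x - target)) > 1e-8)
    stop("design ", paste(design, collapse = " vs "),
         " is not expressible in the basic contrasts", call. = FALSE)
  xr <- round(x)
  if (max(abs(x - xr)) > 1e-8 || any(!xr %in% c(-1, 0, 1)))
    stop("contrast for ", assigned, " vs ", d$reference,
         " is not a -1/0/1 combination of the basic contrasts", call. = FALSE)
  as.numeric(xr)
}

match_design <- function(network, design) {
  design <- sort(as.character(design))
  for (d in network$designs)
    if (identical(sort(d$treatments), design)) return(d)
  stop("design ", paste(design, collapse = " vs "),
       " not declared in the network", call. = FALSE)
}

# the two-arm design {b, c} closing a loop c(apex, b, c), plus the indices of
# the two basic-contrast columns whose product codes the inconsistency term
loop_closing_design <- function(network, loop) {
  b <- loop[2]; c_ <- loop[3]
  if (network$reference %in% c(b, c_))
    stop("loop closing pair must not contain the network reference",
         call. = FALSE)
  hit <- NULL
  for (d in network$designs)
    if (identical(sort(d$treatments), sort(c(b, c_)))) hit <- d
  if (is.null(hit))
    stop("no loop: network has no two-arm design ", b, " vs ", c_,
         call. = FALSE)
  cb <- build_contrasts(network, hit$treatments,
                        setdiff(hit$treatments, hit$reference))
  cols <- which(cb != 0)
  if (length(cols) != 2)
    stop("loop-closing design does not touch exactly two basic contrasts",
         call. = FALSE)
  list(design = hit, cols = cols)
}
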