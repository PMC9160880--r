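# ---- GC-MS fragment measurement model --------------------------------------
#
# Proteinogenic amino acids are derivatized (TBDMS-style) before GC-MS, so
# a measured fragment carries, besides its carbon backbone, extra C/H/N/O/
# Si/S atoms whose natural heavy isotopes inflate the observed mass
# distribution. The correction matrix maps the backbone MID (what the flux
# model predicts) to the observed MID; correction inverts that map under a
# non-negativity constraint.

#' Default natural isotope abundance table
#'
#' Terrestrial natural abundances for the isotopes relevant to TBDMS
#' derivatization chemistry, as mass-shift distributions (M+0, M+1, ...):
#' 13C 0.0107, 2H 0.000115, 15N 0.00364, 17O/18O, 29Si/30Si, 33S/34S/36S.
#'
#' @return Named list of numeric vectors, one per element.
#' @export
default_isotope_abundances <- function() {
  list(C = c(0.9893, 0.0107),
       H = c(0.999885, 0.000115),
       N = c(0.99636, 0.00364),
       O = c(0.99757, 0.00038, 0.00205),
       Si = c(0.92223, 0.04685, 0.03092),
       S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
}

#' Define a measured fragment
#'
#' @param id Fragment id (e.g. `"Ala_57"`-style labels).
#' @param amino_acid Amino acid (or analyte) name, informational.
#' @param precursors List of `list(met =, positions =)`: the precursor
#'   metabolite(s) and the backbone carbon positions retained in the
#'   fragment. Fragments spanning several precursors predict the
#'   convolution of the corresponding EMU MIDs.
#' @param formula Named integer vector of non-backbone atom counts
#'   (derivatization plus any amino-acid atoms outside the retained
#'   backbone), e.g. `c(C = 8, H = 26, N = 1, O = 1, Si = 2)`.
#' @return A `fragment_def`.
#' @export
fragment_def <- function(id, amino_acid, precursors, formula = integer()) {
  if (length(formula) && (is.null(names(formula)) || any(formula < 0)))
    stop("formula must be a named vector of non-negative atom counts")
  structure(list(id = id, amino_acid = amino_acid,
                 precursors = precursors,
                 formula = formula), class = "fragment_def")
}

#' Synthetic-default fragment library for the toy networks
#'
#' A small library of amino-acid-style fragments mapping to EMUs of the
#' built-in networks, with TBDMS-like derivatization formulas. This is a
#' synthetic default for testing and simulation, not a published fragment
#' list; real analyses should load their own library
#' ([read_fragment_library()]).
#'
#' @param preset Network preset id.
#' @return List of `fragment_def`.
#' @export
toy_fragment_library <- function(preset = c("TOY1", "TOY_CMP")) {
  preset <- match.arg(preset)
  tbdms1 <- c(C = 8, H = 26, N = 1, O = 1, Si = 2)
  tbdms2 <- c(C = 14, H = 36, N = 1, O = 2, Si = 2)
  switch(preset,
    TOY1 = list(
      fragment_def("FragB", "ala-like", list(list(met = "B", positions = 1:2)), tbdms1),
      fragment_def("FragC", "gly-like", list(list(met = "C", positions = 1)), tbdms1)),
    TOY_CMP = list(
      fragment_def("FragP", "ala-like", list(list(met = "P", positions = 1:2)), tbdms1),
      fragment_def("FragG", "ser-like", list(list(met = "G", positions = 1:3)), tbdms2),
      fragment_def("FragR", "gly-like", list(list(met = "R", positions = 1:2)), tbdms1),
      fragment_def("FragT", "glu-like", list(list(met = "T", positions = 1:3)), tbdms2),
      fragment_def("FragT23", "glu-like", list(list(met = "T", positions = 2:3)), tbdms1)))
}

#' Read / write a fragment library (YAML)
#'
#' @param path File path.
#' @return `read_fragment_library`: list of `fragment_def`.
#' @export
read_fragment_library <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y$fragments, function(f)
    fragment_def(f$id, f$amino_acid,
                 lapply(f$precursors, function(p)
                   list(met = p$met, positions = as.integer(p$positions))),
                 unlist(f$formula)))
}

#' @rdname read_fragment_library
#' @param fragments List of `fragment_def`.
#' @export
write_fragment_library <- function(fragments, path) {
  y <- list(fragments = lapply(fragments, function(f)
    list(id = f$id, amino_acid = f$amino_acid,
         precursors = lapply(f$precursors, function(p)
           list(met = p$met, positions = p$positions)),
         formula = as.list(f$formula))))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Natural-abundance correction matrix
#'
#' Builds the matrix `M` such that `observed = M %*% backbone_mid`: every
#' column is the natural isotope mass-shift kernel of the fragment's
#' non-backbone atoms, shifted by the backbone mass. Columns sum to at
#' most 1 because the observed mass window is truncated at
#' `window` channels.
#'
#' @param fragment A `fragment_def` (its `formula` supplies atom counts).
#' @param backbone_carbons Number of backbone carbons (the predicted MID
#'   has `backbone_carbons + 1` channels).
#' @param window Number of observed mass channels (default
#'   `backbone_carbons + 1`).
#' @param abundances Isotope abundance table,
#'   [default_isotope_abundances()].
#' @return `window x (backbone_carbons + 1)` matrix.
#' @export
natural_abundance_matrix <- function(fragment, backbone_carbons,
                                     window = backbone_carbons + 1L,
                                     abundances = default_isotope_abundances()) {
  counts <- fragment$formula
  if (length(counts) && any(counts < 0)) stop("negative element counts")
  kernel <- 1
  for (el in names(counts)) {
    if (counts[[el]] == 0) next
    dist <- abundances[[el]]
    if (is.null(dist)) stop("no abundance data for element ", el)
    for (i in seq_len(counts[[el]])) kernel <- convolve_mid(kernel, dist)
  }
  M <- matrix(0, window, backbone_carbons + 1L)
  for (j in 0:backbone_carbons) {
    idx <- seq_along(kernel) + j
    keep <- idx <= window
    M[idx[keep], j + 1L] <- kernel[keep]
  }
  M
}

#' Apply a correction matrix to a backbone MID
#'
#' @param M Correction matrix from [natural_abundance_matrix()].
#' @param mid Backbone MID vector.
#' @return Observed MID (length `nrow(M)`).
#' @export
apply_abundance_matrix <- function(M, mid) drop(M %*% mid)

#' Measured MID container
#'
#' @param fragment Fragment id.
#' @param fractions Mass fractions (M+0 ...). Must sum to 1 within
#'   `tolerance` (intensity windows truncate heavy tails); stored
#'   renormalized.
#' @param sd Per-channel standard deviations (> 0); scalar recycled.
#'   Defaults to 0.003 mass fractions when not supplied.
#' @param replicate Replicate count.
#' @param tolerance Allowed deviation of `sum(fractions)` from 1.
#' @return A `measured_mid`.
#' @export
measured_mid <- function(fragment, fractions, sd = 0.003, replicate = 1L,
                         tolerance = 0.02) {
  if (any(fractions < 0)) stop("mass fractions must be >= 0")
  if (abs(sum(fractions) - 1) > tolerance)
    stop(sprintf("fractions of '%s' sum to %.3f (tolerance %.2f)",
                 fragment, sum(fractions), tolerance))
  sd <- rep_len(sd, length(fractions))
  if (any(sd <= 0)) stop("SDs must be > 0")
  structure(list(fragment = fragment,
                 fractions = fractions / sum(fractions),
                 sd = sd, replicate = as.integer(replicate)),
            class = "measured_mid")
}

#' Correct an observed MID for natural abundance
#'
#' Solves `M x = observed` for `x >= 0` by non-negative least squares and
#' renormalizes to sum 1. Warns when `M` is ill-conditioned (condition
#' number > 1e8).
#'
#' @param observed A `measured_mid` or numeric vector.
#' @param M Correction matrix.
#' @return Corrected backbone MID (numeric, sums to 1).
#' @export
correct_mid <- function(observed, M) {
  y <- if (inherits(observed, "measured_mid")) observed$fractions else observed
  if (length(y) != nrow(M)) stop("dimension mismatch between MID and matrix")
  if (kappa(M) > 1e8)
    warning("correction matrix is ill-conditioned (condition number > 1e8)")
  x <- pracma::lsqnonneg(M, y)$x
  if (sum(x) <= 0) stop("correction produced an all-zero MID")
  x / sum(x)
}

#' Map a fragment to the EMUs that predict its backbone MID
#'
#' @param fragment A `fragment_def`.
#' @param net The `metabolic_network` the precursors live in.
#' @return List of EMUs ([emu()]); the fragment's backbone MID is the
#'   convolution of their simulated MIDs.
#' @export
map_fragment_to_emus <- function(fragment, net) {
  lapply(fragment$precursors, function(p) {
    i <- match(p$met, net$metabolites$id)
    if (is.na(i))
      stop("fragment '", fragment$id, "' precursor '", p$met,
           "' is not in the network")
    if (any(p$positions < 1) || any(p$positions > net$metabolites$n_carbons[i]))
      stop("fragment '", fragment$id, "' retains invalid positions of ", p$met)
    emu(p$met, p$positions)
  })
}

#' Read / write measured-MID tables (CSV)
#'
#' Long format with columns `fragment, mass_shift, fraction, sd,
#' replicate`.
#'
#' @param path File path.
#' @return `read_mid_table`: named list of `measured_mid`.
#' @export
read_mid_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fragment", "mass_shift", "fraction", "sd", "replicate")
  if (!all(need %in% names(d))) stop("MID table must have columns: ",
                                     paste(need, collapse = ", "))
  out <- lapply(split(d, d$fragment), function(g) {
    g <- g[order(g$mass_shift), ]
    measured_mid(g$fragment[1], g$fraction, g$sd, g$replicate[1])
  })
  out[unique(d$fragment)]
}

#' @rdname read_mid_table
#' @param mids Named list of `measured_mid`.
#' @export
write_mid_table <- function(mids, path) {
  rows <- do.call(rbind, lapply(mids, function(m)
    data.frame(fragment = m$fragment,
               mass_shift = seq_along(m$fractions) - 1L,
               fraction = m$fractions, sd = m$sd, replicate = m$replicate)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
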