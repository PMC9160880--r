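# ---- carbon-atom-mapped metabolic networks ---------------------------------

#' Parse a carbon-atom-mapped metabolic network
#'
#' Reads a plain-text atom-transition model. The dialect has one declaration
#' or reaction per line:
#' \preformatted{
#'   # comment
#'   met <id> <n_carbons> <role>          # role: balanced | substrate | sink
#'   v1: A (ab) -> B (ab)
#'   v2: B (ab) -> C (a) + D (b)
#'   iso: R (ab) <-> P (ab)               # "<->" marks a reversible reaction
#' }
#' Each metabolite term carries an atom map in parentheses, one lowercase
#' letter per carbon; every letter on the substrate side must appear exactly
#' once on the product side and vice versa (carbon conservation). Metabolites
#' with `role = substrate` feed label into the system and `role = sink`
#' metabolites leave it; neither is balanced at steady state. Optional flux
#' bounds may follow a reaction as `[lb, ub]` (mmol gDCW^-1 h^-1).
#'
#' @param text Character scalar (whole file) or character vector of lines.
#' @return An object of class `metabolic_network` with elements
#'   `metabolites` (data.frame: id, n_carbons, role) and `reactions`
#'   (list of reactions, each with id, substrates, products, reversible,
#'   lb, ub).
#' @export
parse_network <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  mets <- list()
  rxns <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^met\\s", line)) {
      f <- strsplit(line, "\\s+")[[1]]
      if (length(f) != 4L)
        stop(sprintf("line %d: malformed metabolite declaration: '%s'", i, line))
      n <- suppressWarnings(as.integer(f[3]))
      if (is.na(n) || n < 0L)
        stop(sprintf("line %d: n_carbons must be an integer >= 0", i))
      if (!f[4] %in% c("balanced", "substrate", "sink"))
        stop(sprintf("line %d: unknown role '%s'", i, f[4]))
      mets[[f[2]]] <- list(id = f[2], n_carbons = n, role = f[4])
    } else if (grepl(":", line, fixed = TRUE)) {
      rxn <- parse_reaction_line(line, i)
      rxns[[rxn$id]] <- rxn
    } else {
      stop(sprintf("line %d: cannot parse '%s'", i, line))
    }
  }
  met_df <- data.frame(
    id = vapply(mets, `[[`, "", "id"),
    n_carbons = vapply(mets, `[[`, 0L, "n_carbons"),
    role = vapply(mets, `[[`, "", "role"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (anyDuplicated(met_df$id))
    stop("duplicate metabolite id")
  if (anyDuplicated(names(rxns)))
    stop("duplicate reaction id")
  net <- structure(list(metabolites = met_df, reactions = unname(rxns)),
                   class = "metabolic_network")
  check_references(net)
  viol <- validate_atom_balance(net)
  if (length(viol))
    stop("atom-balance violations:\n  ", paste(viol, collapse = "\n  "))
  net
}

parse_reaction_line <- function(line, lineno) {
  m <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
  id <- trimws(m[2])
  body <- m[3]
  bounds <- c(NA_real_, NA_real_)
  bm <- regmatches(body, regexec("\\[\\s*([-0-9.eE]+)\\s*,\\s*([-0-9.eE]+)\\s*\\]\\s*$", body))[[1]]
  if (length(bm)) {
    bounds <- as.numeric(bm[2:3])
    body <- sub("\\[.*\\]\\s*$", "", body)
  }
  reversible <- grepl("<->", body, fixed = TRUE)
  sides <- strsplit(body, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop(sprintf("line %d: reaction '%s' needs exactly one arrow", lineno, id))
  parse_side <- function(s) {
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    lapply(terms, function(t) {
      t <- trimws(t)
      tm <- regmatches(t, regexec("^([A-Za-z0-9_]+)\\s*\\(([a-z]*)\\)$", t))[[1]]
      if (!length(tm))
        stop(sprintf("line %d: malformed term '%s' in reaction '%s'", lineno, t, id))
      list(met = tm[2], map = tm[3])
    })
  }
  if (is.na(bounds[1])) bounds <- if (reversible) c(-1000, 1000) else c(0, 1000)
  if (bounds[1] > bounds[2])
    stop(sprintf("line %d: lower bound exceeds upper bound", lineno))
  list(id = id, substrates = parse_side(sides[1]), products = parse_side(sides[2]),
       reversible = reversible, lb = bounds[1], ub = bounds[2])
}

check_references <- function(net) {
  ids <- net$metabolites$id
  for (r in net$reactions) {
    for (term in c(r$substrates, r$products)) {
      if (!term$met %in% ids)
        stop(sprintf("reaction '%s' references undeclared metabolite '%s'",
                     r$id, term$met))
      nc <- net$metabolites$n_carbons[match(term$met, ids)]
      if (nchar(term$map) != nc)
        stop(sprintf("reaction '%s': atom map '%s' has %d letters but '%s' has %d carbons",
                     r$id, term$map, nchar(term$map), term$met, nc))
    }
  }
  invisible(net)
}

#' Serialize a metabolic network back to its text dialect
#'
#' Inverse of [parse_network()]: `parse_network(serialize_network(net))`
#' yields an equivalent network.
#'
#' @param net A `metabolic_network`.
#' @return Character scalar.
#' @export
serialize_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  met_lines <- sprintf("met %s %d %s", net$metabolites$id,
                       net$metabolites$n_carbons, net$metabolites$role)
  side <- function(terms)
    paste(vapply(terms, function(t) sprintf("%s (%s)", t$met, t$map), ""),
          collapse = " + ")
  rxn_lines <- vapply(net$reactions, function(r) {
    arrow <- if (r$reversible) "<->" else "->"
    sprintf("%s: %s %s %s [%g, %g]", r$id, side(r$substrates), arrow,
            side(r$products), r$lb, r$ub)
  }, "")
  paste(c(met_lines, rxn_lines), collapse = "\n")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites, %d reactions (%d reversible)\n",
              nrow(x$metabolites), length(x$reactions),
              sum(vapply(x$reactions, `[[`, FALSE, "reversible"))))
  invisible(x)
}

#' Check carbon conservation of every reaction
#'
#' A reaction conserves carbon when each atom letter occurs exactly once on
#' the substrate side and exactly once on the product side.
#'
#' @param net A `metabolic_network`.
#' @return Character vector of human-readable violations (empty if none).
#' @export
validate_atom_balance <- function(net) {
  viol <- character()
  for (r in net$reactions) {
    sub_letters <- unlist(strsplit(vapply(r$substrates, `[[`, "", "map"), ""))
    prod_letters <- unlist(strsplit(vapply(r$products, `[[`, "", "map"), ""))
    if (anyDuplicated(sub_letters))
      viol <- c(viol, sprintf("reaction '%s': duplicate substrate atom letter", r$id))
    if (anyDuplicated(prod_letters))
      viol <- c(viol, sprintf("reaction '%s': duplicate product atom letter", r$id))
    miss <- setdiff(sub_letters, prod_letters)
    extra <- setdiff(prod_letters, sub_letters)
    if (length(miss))
      viol <- c(viol, sprintf("reaction '%s': substrate letter(s) %s unplaced on product side",
                              r$id, paste(miss, collapse = ",")))
    if (length(extra))
      viol <- c(viol, sprintf("reaction '%s': product letter(s) %s missing on substrate side",
                              r$id, paste(extra, collapse = ",")))
  }
  viol
}

#' Stoichiometric matrix over balanced metabolites
#'
#' @param net A `metabolic_network`.
#' @return Numeric matrix, one row per `balanced` metabolite (rownames),
#'   one column per reaction (colnames); entries are net stoichiometric
#'   coefficients. Substrate- and sink-role metabolites are excluded from
#'   steady-state balancing and carry no row.
#' @export
stoichiometric_matrix <- function(net) {
  bal <- net$metabolites$id[net$metabolites$role == "balanced"]
  rids <- vapply(net$reactions, `[[`, "", "id")
  S <- matrix(0, nrow = length(bal), ncol = length(rids),
              dimnames = list(bal, rids))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    for (t in r$substrates)
      if (t$met %in% bal) S[t$met, j] <- S[t$met, j] - 1
    for (t in r$products)
      if (t$met %in% bal) S[t$met, j] <- S[t$met, j] + 1
  }
  S
}

#' Dimension of the free-flux space under equality constraints
#'
#' Computes the dimension of the affine solution space of the steady-state
#' system `S v = 0` intersected with linear equality constraints that fix
#' individual net fluxes (measured uptake/secretion rates, biomass
#' effluxes). Exchange fluxes of reversible reactions are additional free
#' parameters and are added to the count.
#'
#' @param net A `metabolic_network`.
#' @param constraints Named numeric vector: `c(upt = 5.9, ...)` fixes the
#'   named net fluxes to the given values.
#' @return Integer dimension (net null-space dimension + number of
#'   reversible reactions).
#' @export
free_flux_dimension <- function(net, constraints = NULL) {
  sys <- constrained_system(net, constraints)
  n_rxn <- length(net$reactions)
  n_rev <- sum(vapply(net$reactions, `[[`, FALSE, "reversible"))
  n_rxn - sys$rank + n_rev
}

# Build [S; E] v = [0; b]; check consistency; return coefficient matrix,
# rhs, rank, a particular (min-norm) solution and a null-space basis.
constrained_system <- function(net, constraints = NULL, tol = 1e-8) {
  S <- stoichiometric_matrix(net)
  rids <- colnames(S)
  E <- NULL; b <- numeric()
  if (length(constraints)) {
    if (is.null(names(constraints)) || any(!nzchar(names(constraints))))
      stop("constraints must be a named numeric vector of reaction fluxes")
    bad <- setdiff(names(constraints), rids)
    if (length(bad))
      stop("constraint on unknown reaction(s): ", paste(bad, collapse = ", "))
    E <- matrix(0, length(constraints), length(rids),
                dimnames = list(NULL, rids))
    for (k in seq_along(constraints)) E[k, names(constraints)[k]] <- 1
    b <- unname(constraints)
  }
  M <- rbind(S, E)
  rhs <- c(rep(0, nrow(S)), b)
  if (nrow(M) == 0L)
    return(list(M = M, rhs = rhs, rank = 0L, v0 = rep(0, ncol(M)),
                N = diag(ncol(M)), reaction_ids = rids))
  sv <- svd(M)
  rank <- sum(sv$d > max(dim(M)) * max(sv$d, 0) * 1e-12)
  v0 <- MASS::ginv(M) %*% rhs
  if (max(abs(M %*% v0 - rhs)) > tol * max(1, max(abs(rhs))))
    stop("infeasible constraints: steady-state system has no solution")
  N <- MASS::Null(t(M))
  if (!length(N)) N <- matrix(0, ncol(M), 0)
  list(M = M, rhs = rhs, rank = rank, v0 = drop(v0), N = N, reaction_ids = rids)
}
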