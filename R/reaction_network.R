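#' Define a molecular species
#'
#' A species is a node of a reaction network: a monomer, a multi-protein
#' complex, or a fused (post-fusion) complex. Every species carries a moiety
#' composition -- how many copies of each underlying protein it contains --
#' so that conservation laws and the fusion readout are structural properties
#' of the model rather than user configuration.
#'
#' @param name Unique identifier string.
#' @param moieties Named integer vector mapping protein name to copy number;
#'   all counts non-negative, at least one positive.
#' @param role One of \code{"monomer"}, \code{"complex"}, \code{"fused"}.
#' @return An object of class \code{ssnm_species}.
#' @examples
#' species("yT", c(ySyx = 1, yS25 = 1), role = "complex")
#' @export
species <- function(name, moieties, role = c("monomer", "complex", "fused")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(moieties)) || any(!nzchar(names(moieties))))
    stop("moieties must be a named vector of protein counts")
  m <- as.numeric(moieties)
  if (any(m < 0) || any(m != round(m)))
    stop("moiety counts must be non-negative integers")
  if (!any(m > 0))
    stop("species '", name, "' must contain at least one protein moiety")
  structure(list(name = name,
                 moieties = stats::setNames(as.integer(m), names(moieties)),
                 role = role),
            class = "ssnm_species")
}

#' Define a mass-action reaction
#'
#' Reversible reactions are stored as a single record with forward and
#' reverse rate constants; \code{kr = 0} encodes an irreversible reaction.
#' Units are per second for unimolecular steps and per micromolar per second
#' for bimolecular steps.
#'
#' @param label Unique reaction identifier (e.g. \code{"R1"}).
#' @param reactants,products Named integer vectors mapping species name to
#'   stoichiometric coefficient (positive integers); both non-empty.
#' @param kf,kr Forward and reverse rate constants, both \code{>= 0} with at
#'   least one positive.
#' @return An object of class \code{ssnm_reaction}.
#' @examples
#' reaction("R1", c(A = 1, B = 1), c(C = 1), kf = 1, kr = 0.1)
#' @export
reaction <- function(label, reactants, products, kf, kr = 0) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  chk <- function(x, what) {
    if (length(x) == 0L || is.null(names(x)))
      stop("reaction '", label, "': ", what, " must be a non-empty named vector")
    v <- as.numeric(x)
    if (any(v <= 0) || any(v != round(v)))
      stop("reaction '", label, "': ", what,
           " stoichiometric coefficients must be positive integers")
    stats::setNames(as.integer(v), names(x))
  }
  reactants <- chk(reactants, "reactants")
  products <- chk(products, "products")
  if (!is.finite(kf) || !is.finite(kr) || kf < 0 || kr < 0)
    stop("reaction '", label, "': rate constants must be finite and >= 0")
  if (kf == 0 && kr == 0)
    stop("reaction '", label, "': at least one of kf, kr must be positive")
  structure(list(label = label, reactants = reactants, products = products,
                 kf = kf, kr = kr),
            class = "ssnm_reaction")
}

#' Assemble a reaction-network model
#'
#' @param name Model name.
#' @param species List of \code{\link{species}} objects.
#' @param reactions List of \code{\link{reaction}} objects.
#' @param initial Named numeric vector of initial concentrations (micromolar);
#'   species not named start at 0.
#' @param readout_moiety Protein name whose fused fraction defines the fusion
#'   level (conventionally the v-SNARE).
#' @param validate Run \code{\link{validate_model}} and stop on violations.
#' @return An object of class \code{ssnm_model}.
#' @export
network_model <- function(name, species, reactions, initial = numeric(),
                          readout_moiety, validate = TRUE) {
  sp_names <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(sp_names))
    stop("duplicate species names: ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "))
  names(species) <- sp_names
  rx_labels <- vapply(reactions, function(r) r$label, character(1))
  if (anyDuplicated(rx_labels))
    stop("duplicate reaction labels: ",
         paste(unique(rx_labels[duplicated(rx_labels)]), collapse = ", "))
  names(reactions) <- rx_labels
  init <- stats::setNames(numeric(length(sp_names)), sp_names)
  if (length(initial)) {
    init[names(initial)] <- as.numeric(initial)
  }
  m <- structure(list(name = name, species = species, reactions = reactions,
                      initial = init, readout_moiety = readout_moiety),
                 class = "ssnm_model")
  if (validate) {
    v <- validate_model(m)
    if (length(v))
      stop("invalid model '", name, "':\n  ",
           paste(vapply(v, `[[`, character(1), "message"), collapse = "\n  "))
  }
  m
}

#' @export
print.ssnm_model <- function(x, ...) {
  cat("SSNM reaction-network model:", x$name, "\n")
  cat("  species:  ", length(x$species), "\n")
  cat("  reactions:", length(x$reactions),
      sprintf("(%s)", paste(names(x$reactions), collapse = ", ")), "\n")
  cat("  readout moiety:", x$readout_moiety, "\n")
  nz <- x$initial[x$initial > 0]
  if (length(nz))
    cat("  nonzero initials (uM):",
        paste(sprintf("%s=%g", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' List of protein moieties appearing in a model
#' @param model An \code{ssnm_model}.
#' @return Character vector of protein names.
#' @export
model_proteins <- function(model) {
  unique(unlist(lapply(model$species, function(s) names(s$moieties))))
}

# Reactant (R), product (P) and net (S = P - R) stoichiometric matrices,
# species x reactions, in declaration order.
stoich_matrices <- function(model) {
  sp <- names(model$species)
  rx <- names(model$reactions)
  R <- P <- matrix(0L, length(sp), length(rx), dimnames = list(sp, rx))
  for (r in model$reactions) {
    ok <- names(r$reactants) %in% sp
    R[names(r$reactants)[ok], r$label] <- r$reactants[ok]
    ok <- names(r$products) %in% sp
    P[names(r$products)[ok], r$label] <- r$products[ok]
  }
  list(R = R, P = P, S = P - R)
}

# species x proteins moiety matrix
moiety_matrix <- function(model) {
  prot <- model_proteins(model)
  sp <- names(model$species)
  M <- matrix(0L, length(sp), length(prot), dimnames = list(sp, prot))
  for (s in model$species) M[s$name, names(s$moieties)] <- s$moieties
  M
}

#' Validate a reaction-network model
#'
#' Checks the structural invariants of the model and returns violations as
#' data (one record per broken invariant), never as exceptions: undeclared
#' species referenced by reactions or initial concentrations, moiety
#' imbalance across a reaction (fusion is a state change, so every protein
#' must be conserved by every reaction), negative rates or initial
#' concentrations, and an undeclared readout moiety.
#'
#' @param model An \code{ssnm_model}.
#' @return A list of violation records, each with fields \code{type},
#'   \code{where} and \code{message}; empty when the model is valid.
#' @examples
#' validate_model(yeast_ssnm())  # list()
#' @export
validate_model <- function(model) {
  violations <- list()
  flag <- function(type, where, message) {
    violations[[length(violations) + 1L]] <<-
      list(type = type, where = where, message = message)
  }
  sp <- names(model$species)
  for (r in model$reactions) {
    undecl <- setdiff(c(names(r$reactants), names(r$products)), sp)
    for (u in undecl)
      flag("undeclared_species", r$label,
           sprintf("reaction %s references undeclared species '%s'", r$label, u))
    if (r$kf < 0 || r$kr < 0)
      flag("negative_rate", r$label,
           sprintf("reaction %s has a negative rate constant", r$label))
    if (length(undecl) == 0L) {
      # moiety balance, per protein
      tot <- function(side) {
        out <- numeric(0)
        for (nm in names(side)) {
          mo <- model$species[[nm]]$moieties * side[[nm]]
          for (p in names(mo)) out[p] <- (if (p %in% names(out)) out[p] else 0) + mo[[p]]
        }
        out
      }
      tr <- tot(r$reactants); tp <- tot(r$products)
      prots <- union(names(tr), names(tp))
      for (p in prots) {
        a <- if (p %in% names(tr)) tr[[p]] else 0
        b <- if (p %in% names(tp)) tp[[p]] else 0
        if (a != b)
          flag("moiety_imbalance", r$label,
               sprintf("reaction %s does not conserve protein '%s' (%d vs %d)",
                       r$label, p, a, b))
      }
    }
  }
  undecl_init <- setdiff(names(model$initial), sp)
  for (u in undecl_init)
    flag("undeclared_species", "initial_concentrations",
         sprintf("initial concentration given for undeclared species '%s'", u))
  neg <- names(model$initial)[model$initial < 0]
  for (u in neg)
    flag("negative_concentration", u,
         sprintf("initial concentration of '%s' is negative", u))
  if (!model$readout_moiety %in% model_proteins(model))
    flag("unknown_readout", model$readout_moiety,
         sprintf("readout moiety '%s' is not a protein of any species",
                 model$readout_moiety))
  violations
}

#' Extract the rate set carried by a model's reactions
#'
#' @param model An \code{ssnm_model}.
#' @return Named list mapping reaction label to a numeric vector
#'   \code{c(kf = , kr = )}.
#' @export
rate_set <- function(model) {
  lapply(model$reactions, function(r) c(kf = r$kf, kr = r$kr))
}

# Align a rate set against a model, erroring on any missing label.
check_rates <- function(model, rates) {
  missing <- setdiff(names(model$reactions), names(rates))
  if (length(missing))
    stop("rate set is missing reaction label(s): ",
         paste(missing, collapse = ", "))
  for (lb in names(model$reactions)) {
    k <- rates[[lb]]
    if (length(k) < 2L || any(!is.finite(k[1:2])) || any(k[1:2] < 0))
      stop("rates for reaction '", lb, "' must be finite c(kf, kr) >= 0")
  }
  rates
}

#' Compile a model to its mass-action ODE right-hand side
#'
#' For each reaction the net flux is
#' \code{kf * prod(reactant conc ^ stoich) - kr * prod(product conc ^ stoich)}
#' and each species' time derivative is the signed stoichiometric sum of
#' fluxes. The returned closure is deterministic and side-effect free.
#'
#' @param model A valid \code{ssnm_model}.
#' @param rates Rate set covering every reaction label (default: the rates
#'   carried by the model's reactions).
#' @return A function \code{f(conc)} mapping a named (or declaration-ordered)
#'   concentration vector to the named derivative vector (uM/s).
#' @examples
#' f <- build_mass_action_rhs(yeast_ssnm())
#' f(yeast_ssnm()$initial)
#' @export
build_mass_action_rhs <- function(model, rates = rate_set(model)) {
  v <- validate_model(model)
  if (length(v))
    stop("model has validation violations; see validate_model()")
  rates <- check_rates(model, rates)
  st <- stoich_matrices(model)
  kf <- vapply(names(model$reactions), function(lb) rates[[lb]][["kf"]], numeric(1))
  kr <- vapply(names(model$reactions), function(lb) rates[[lb]][["kr"]], numeric(1))
  Rm <- st$R; Pm <- st$P; Sm <- st$S
  sp <- rownames(Sm)
  function(conc) {
    y <- if (is.null(names(conc))) stats::setNames(conc, sp) else conc[sp]
    # product of y_i^c_ij down each column; columns with no entries give 1
    fwd <- kf * apply(Rm, 2L, function(c) prod(y^c))
    rev <- kr * apply(Pm, 2L, function(c) prod(y^c))
    drop(Sm %*% (fwd - rev))
  }
}

#' Moiety conservation laws of a model
#'
#' Every protein moiety yields one conserved linear combination: the total
#' amount of that protein summed over all species containing it, weighted by
#' copy number, is invariant along any trajectory because every reaction
#' conserves every protein (fusion is a state change, not destruction).
#' Coefficient vectors are rows of the left null space of the stoichiometric
#' matrix.
#'
#' @param model A valid \code{ssnm_model}.
#' @return A list with one element per protein: fields \code{protein},
#'   \code{coefficients} (named numeric over species) and \code{total}
#'   (the conserved value under the model's initial concentrations, uM).
#' @examples
#' length(conservation_laws(yeast_ssnm()))  # 4
#' @export
conservation_laws <- function(model) {
  M <- moiety_matrix(model)
  lapply(colnames(M), function(p) {
    coef <- M[, p]
    list(protein = p,
         coefficients = coef,
         total = sum(coef * model$initial))
  })
}

#' Delete a reaction from a model (in-silico mutation)
#'
#' Returns a new model identical to the input except that the labeled
#' reaction is absent; the species list and initial concentrations are
#' unchanged and the input model is not modified. This is the in-silico
#' analogue of a binding-site mutation that abolishes one interaction, e.g.
#' the open-syntaxin mutant that removes the closed Munc18-syntaxin binding
#' mode from the wildtype neuronal motif.
#'
#' @param model An \code{ssnm_model}.
#' @param label Label of the reaction to delete.
#' @return A new \code{ssnm_model}.
#' @examples
#' remove_reaction(neuronal_ssnm(), "R6")
#' @export
remove_reaction <- function(model, label) {
  if (!label %in% names(model$reactions))
    stop("unknown reaction label '", label, "'; available: ",
         paste(names(model$reactions), collapse = ", "))
  model$reactions[[label]] <- NULL
  model$name <- paste0(model$name, "_minus_", label)
  model
}
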