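#' Four-species MSC model
#'
#' Defines the species tree `(((A,B),C),O)` with split times in
#' generations, diploid effective population sizes per branch
#' (Wright-Fisher individuals), and a per-generation mutation rate.
#' Roles `A`, `B`, `C`, `O` are fixed: `A` and `B` are the ingroup cherry
#' of the species tree, `C` the third ingroup taxon, `O` the outgroup.
#'
#' The derived internal branch ("internode") between the `(A,B)` split
#' and the `((A,B),C)` split, in coalescent units of 2N generations, is
#' `(tau_ABC - tau_AB) / (2 * N_AB)`; it governs the expected level of
#' gene-tree discordance (see [match_probability()]).
#'
#' Default split times follow the Neotropical-primate calibration used for
#' the demography experiments (`tau_AB` = 1.6e6, `tau_ABC` = 1.75e6
#' generations); the default effective sizes of 2.5e5 put the internode at
#' 0.3 coalescent units, the scale previously reported for that radiation.
#'
#' @param taxon_labels Character vector of 4 names bound to roles A,B,C,O.
#' @param tau_AB,tau_ABC,tau_root Split times in generations,
#'   `0 < tau_AB < tau_ABC < tau_root`.
#' @param N Named numeric vector of diploid effective sizes for branches
#'   `A`, `B`, `C`, `O`, `AB`, `ABC`, `root`; a single number is recycled.
#' @param mu Substitution rate per site per generation.
#' @return An object of class `species_tree_model`.
#' @examples
#' m <- species_tree_model()
#' internode_units(m)
#' model_with_internode(m, 0.1924)
#' @export
species_tree_model <- function(taxon_labels = c("A", "B", "C", "O"),
                               tau_AB = 1.6e6, tau_ABC = 1.75e6,
                               tau_root = 5.8e6,
                               N = 2.5e5, mu = 1e-8) {
  if (length(taxon_labels) != 4L || anyDuplicated(taxon_labels))
    .stopf("taxon_labels must be 4 distinct names (roles A, B, C, O)")
  if (!(tau_AB > 0 && tau_AB < tau_ABC && tau_ABC < tau_root))
    .stopf("split times must satisfy 0 < tau_AB < tau_ABC < tau_root")
  branches <- c("A", "B", "C", "O", "AB", "ABC", "root")
  if (length(N) == 1L) N <- setNames(rep(N, 7L), branches)
  if (is.null(names(N)) || !all(branches %in% names(N)))
    .stopf("N must be a single size or a vector named %s",
           paste(branches, collapse = ", "))
  N <- N[branches]
  if (any(!is.finite(N)) || any(N <= 0)) .stopf("all effective sizes must be > 0")
  if (!is.numeric(mu) || mu <= 0) .stopf("mu must be > 0")
  structure(
    list(taxon_labels = setNames(as.character(taxon_labels),
                                 c("A", "B", "C", "O")),
         tau_AB = tau_AB, tau_ABC = tau_ABC, tau_root = tau_root,
         N = N, mu = mu),
    class = "species_tree_model"
  )
}

#' @rdname species_tree_model
#' @param model A `species_tree_model`.
#' @export
internode_units <- function(model) {
  stopifnot(inherits(model, "species_tree_model"))
  (model$tau_ABC - model$tau_AB) / (2 * model$N[["AB"]])
}

#' @rdname species_tree_model
#' @param T Target internode length in coalescent units (`>= 0`); the
#'   effective size of the `(A,B)` ancestral population is rescaled so the
#'   fixed split times yield this internode.  `T = 0` is realised by an
#'   effectively infinite ancestral size.
#' @export
model_with_internode <- function(model, T) {
  stopifnot(inherits(model, "species_tree_model"))
  .check_internode(T)
  dt <- model$tau_ABC - model$tau_AB
  model$N[["AB"]] <- if (T <= 0) 1e15 else dt / (2 * T)
  model
}

#' Model for the unequal-effective-size demography experiment
#'
#' Builds the design used to probe whether large, unequal ancestral
#' population sizes alone can bias quartet gene-tree frequencies: lineage
#' `A` keeps a small fixed size while every other branch (tips `B`, `C`,
#' `O` and all ancestral populations) has size `x`.  With `x` large
#' relative to the split times, essentially all coalescences are pushed
#' into the root population and the three quartet topologies become
#' equally likely.
#'
#' @param x Effective size of all branches other than `A` (the experiment
#'   sweeps `x` over 1e5..1e8).
#' @param N_A Fixed effective size of lineage A (default 1e4).
#' @inheritParams species_tree_model
#' @return A `species_tree_model`.
#' @export
unequal_ne_model <- function(x, N_A = 1e4,
                             tau_AB = 1.6e6, tau_ABC = 1.75e6,
                             tau_root = 5.8e6, mu = 1e-8) {
  species_tree_model(
    tau_AB = tau_AB, tau_ABC = tau_ABC, tau_root = tau_root,
    N = c(A = N_A, B = x, C = x, O = x, AB = x, ABC = x, root = x),
    mu = mu
  )
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat("Four-species MSC model (((A,B),C),O)\n")
  cat(sprintf("  taxa: A=%s B=%s C=%s O=%s\n", x$taxon_labels[1],
              x$taxon_labels[2], x$taxon_labels[3], x$taxon_labels[4]))
  cat(sprintf("  splits (generations): tau_AB=%g tau_ABC=%g tau_root=%g\n",
              x$tau_AB, x$tau_ABC, x$tau_root))
  cat(sprintf("  N: %s\n", paste(sprintf("%s=%g", names(x$N), x$N),
                                 collapse = " ")))
  cat(sprintf("  mu=%g /site/generation; internode = %.4f coalescent units\n",
              x$mu, internode_units(x)))
  invisible(x)
}
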