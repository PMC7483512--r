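#' Ensemble generation settings
#'
#' @param n_strains_per_mfg strains generated per functional group (default
#'   10, giving 100 strains over the ten groups).
#' @param mu_ks_jitter fractional half-width of the uniform multiplicative
#'   perturbation applied per pathway to mu_max and Ks (default 0.10).
#' @param ph_shift_halfwidth half-width (pH units) of the uniform additive
#'   shift applied rigidly to a strain's four pH corners (default 0.2).
#' @param seed integer RNG seed.
#' @return Object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_strains_per_mfg = 10, mu_ks_jitter = 0.10,
                          ph_shift_halfwidth = 0.2, seed = 1L) {
  stopifnot(n_strains_per_mfg >= 1,
            mu_ks_jitter >= 0, mu_ks_jitter < 1,
            ph_shift_halfwidth >= 0)
  structure(list(n_strains_per_mfg = as.integer(n_strains_per_mfg),
                 mu_ks_jitter = mu_ks_jitter,
                 ph_shift_halfwidth = ph_shift_halfwidth,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

## Half-saturation constant in a resource's native unit (base value is g/L).
ks_native <- function(model, resource) {
  r <- model$resources[model$resources$name == resource, ]
  if (r$unit == "g_per_L") model$Ks_g_per_L else model$Ks_g_per_L * 1000 / r$molar_mass
}

#' Generate a stochastic strain ensemble
#'
#' Within each functional group, `n_strains_per_mfg` strains are drawn whose
#' per-pathway maximum growth rates and half-saturation constants vary
#' uniformly within the jitter band around the group values, and whose pH
#' corner set shifts rigidly by a uniform draw. Deterministic under the seed.
#'
#' @param model an `mfg_model` (see [load_parameters()]).
#' @param espec an [ensemble_spec()].
#' @return List of strains (class `strain_ensemble`); each strain is a list
#'   with `mfg`, `index`, `ph_shift`, shifted `ph_corners`, `Ki`,
#'   `initial_biomass` (0 until seeded by [synth_donor()]) and perturbed
#'   `pathways` (each with `mu_max`, `yield`, `substrates`, `products`, `Ks`
#'   per substrate in native units).
#' @export
generate_ensemble <- function(model, espec = ensemble_spec()) {
  stopifnot(inherits(model, "mfg_model"), inherits(espec, "ensemble_spec"))
  set.seed(espec$seed)
  j <- espec$mu_ks_jitter
  strains <- list()
  for (m in model$mfgs) {
    base_ks <- lapply(m$pathways, function(pw)
      vapply(names(pw$substrates), function(r) ks_native(model, r), numeric(1)))
    for (i in seq_len(espec$n_strains_per_mfg)) {
      shift <- stats::runif(1, -espec$ph_shift_halfwidth, espec$ph_shift_halfwidth)
      pws <- lapply(seq_along(m$pathways), function(k) {
        pw <- m$pathways[[k]]
        pw$mu_max <- pw$mu_max * (1 + stats::runif(1, -j, j))
        pw$Ks <- base_ks[[k]] * (1 + stats::runif(1, -j, j))
        pw
      })
      names(pws) <- names(m$pathways)
      strains[[length(strains) + 1L]] <- list(
        mfg = m$id, index = i, ph_shift = shift,
        ph_corners = ph_corners(m$ph_corners[1] + shift, m$ph_corners[2] + shift,
                                m$ph_corners[3] + shift, m$ph_corners[4] + shift),
        Ki = m$Ki, initial_biomass = 0,
        pathways = pws)
    }
  }
  structure(strains, class = "strain_ensemble")
}

#' Donor inoculum profile
#'
#' @param fractions named numeric vector over M1..M10, `>= 0`, summing to 1
#'   (within 1e-9; renormalised exactly).
#' @param label free-text label (e.g. "D2").
#' @return Object of class `donor_profile`.
#' @export
donor_profile <- function(fractions, label = "custom") {
  ids <- paste0("M", 1:10)
  if (!all(ids %in% names(fractions)))
    stop("fractions must be named over M1..M10", call. = FALSE)
  f <- as.numeric(fractions[ids])
  if (any(f < 0)) stop("fractions must be >= 0", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-9)
    stop(sprintf("fractions must sum to 1 (got %.12f)", sum(f)), call. = FALSE)
  structure(list(label = label,
                 mfg_fractions = stats::setNames(f / sum(f), ids)),
            class = "donor_profile")
}

#' @export
print.donor_profile <- function(x, ...) {
  f <- x$mfg_fractions
  cat(sprintf("<donor_profile> %s  (LUB M7+M8: %.2f%%, methanogens M10: %.2f%%)\n",
              x$label, 100 * (f[["M7"]] + f[["M8"]]), 100 * f[["M10"]]))
  print(round(f, 4))
  invisible(x)
}

#' Shipped synthetic donor profiles
#'
#' Functional-group composition vectors emulating the three fecal donors'
#' qualitative structure: a D2-like community with appreciable lactate
#' utilizers (M7+M8 about 1.5%) and 0.6% methanogens, and D7-/D19-like
#' communities with low LUB (0.2% or less) and 0.1% methanogens. These are
#' package-authored synthetic stand-ins (see
#' `extdata/donor_profiles_synthetic.tsv`), not measured compositions.
#'
#' @param donor `"D2"`, `"D7"` or `"D19"`.
#' @return A [donor_profile()].
#' @export
synthetic_donor <- function(donor = c("D2", "D7", "D19")) {
  donor <- match.arg(donor)
  path <- system.file("extdata", "donor_profiles_synthetic.tsv",
                      package = "mfgsim", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$donor == donor, ]
  donor_profile(stats::setNames(tab$fraction, tab$mfg),
                label = paste0(donor, "-like (synthetic)"))
}

#' Seed an ensemble with inoculum biomass
#'
#' Distributes `total` g/L of inoculum across strains: each group receives
#' `total x fraction`, split equally among its member strains.
#'
#' @param ensemble a `strain_ensemble`.
#' @param profile a [donor_profile()].
#' @param total total inoculum biomass, g/L (default 2).
#' @return The ensemble with `initial_biomass` filled in.
#' @export
synth_donor <- function(ensemble, profile, total = 2) {
  stopifnot(inherits(ensemble, "strain_ensemble"),
            inherits(profile, "donor_profile"), total >= 0)
  mfg_of <- vapply(ensemble, `[[`, character(1), "mfg")
  n_per <- table(mfg_of)
  for (k in seq_along(ensemble)) {
    id <- mfg_of[k]
    ensemble[[k]]$initial_biomass <-
      total * profile$mfg_fractions[[id]] / as.integer(n_per[[id]])
  }
  ensemble
}

#' Random donor profile with a pinned lactate-utilizer fraction
#'
#' M7+M8 jointly receive `lub_fraction` (split equally); the remainder is
#' distributed over the other eight groups by a symmetric Dirichlet draw.
#'
#' @param seed integer RNG seed.
#' @param lub_fraction joint M7+M8 fraction in `[0, 1)`.
#' @param alpha Dirichlet concentration for the non-LUB groups (default 1).
#' @return A [donor_profile()].
#' @export
random_profile <- function(seed, lub_fraction, alpha = 1) {
  stopifnot(lub_fraction >= 0, lub_fraction < 1)
  set.seed(as.integer(seed))
  others <- paste0("M", c(1:6, 9, 10))
  g <- stats::rgamma(length(others), shape = alpha)
  f <- stats::setNames(numeric(10), paste0("M", 1:10))
  f[others] <- (1 - lub_fraction) * g / sum(g)
  f[c("M7", "M8")] <- lub_fraction / 2
  donor_profile(f, label = sprintf("random (LUB %.3g%%)", 100 * lub_fraction))
}

#' Rescale a profile's lactate-utilizer fraction
#'
#' Sets the joint M7+M8 fraction to `lub_fraction`, preserving the internal
#' M7:M8 ratio (equal split if both are zero) and renormalising the other
#' groups proportionally. Used for the LUB-abundance sweeps.
#'
#' @param profile a [donor_profile()].
#' @param lub_fraction target joint fraction in `[0, 1)`.
#' @return A [donor_profile()].
#' @export
set_lub_fraction <- function(profile, lub_fraction) {
  stopifnot(inherits(profile, "donor_profile"),
            lub_fraction >= 0, lub_fraction < 1)
  f <- profile$mfg_fractions
  lub0 <- f[["M7"]] + f[["M8"]]
  ratio <- if (lub0 > 0) c(f[["M7"]], f[["M8"]]) / lub0 else c(0.5, 0.5)
  f[c("M7", "M8")] <- lub_fraction * ratio
  rest <- setdiff(names(f), c("M7", "M8"))
  f[rest] <- f[rest] * (1 - lub_fraction) / (1 - lub0)
  donor_profile(f, label = sprintf("%s, LUB %.3g%%", profile$label,
                                   100 * lub_fraction))
}
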