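#' Trapezoidal pH growth response
#'
#' Growth permissivity as a piecewise-linear function of pH defined by four
#' "corner" pH values: zero at or below `c1` and at or above `c4`, one on the
#' plateau `[c2, c3]`, and linear ramps in between. This is the standard
#' corner parameterisation used for functional-group gut community models.
#'
#' @param pH pH value(s), vectorised.
#' @param corners numeric vector or list with elements `c1 <= c2 <= c3 <= c4`
#'   (pH units), e.g. as produced by [ph_corners()].
#' @return Dimensionless factor(s) in `[0, 1]`.
#' @examples
#' ph_growth_factor(6.5, ph_corners(5.3, 6.0, 7.0, 7.5))
#' @export
ph_growth_factor <- function(pH, corners) {
  corners <- as_ph_corners(corners)
  c1 <- corners[["c1"]]; c2 <- corners[["c2"]]
  c3 <- corners[["c3"]]; c4 <- corners[["c4"]]
  f <- numeric(length(pH))
  up <- pH > c1 & pH < c2
  f[up] <- (pH[up] - c1) / (c2 - c1)
  f[pH >= c2 & pH <= c3] <- 1
  dn <- pH > c3 & pH < c4
  f[dn] <- (c4 - pH[dn]) / (c4 - c3)
  f
}

#' pH corner set
#'
#' @param c1,c2,c3,c4 pH units, non-decreasing. Growth is zero outside
#'   `(c1, c4)` and maximal on `[c2, c3]`.
#' @return A named numeric vector of class `ph_corners`.
#' @export
ph_corners <- function(c1, c2, c3, c4) {
  x <- c(c1 = as.numeric(c1), c2 = as.numeric(c2),
         c3 = as.numeric(c3), c4 = as.numeric(c4))
  if (anyNA(x)) stop("pH corners must be numeric and non-missing", call. = FALSE)
  if (is.unsorted(x)) {
    stop(sprintf("invalid pH corner ordering: require c1 <= c2 <= c3 <= c4, got (%s)",
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  class(x) <- "ph_corners"
  x
}

as_ph_corners <- function(x) {
  if (inherits(x, "ph_corners")) return(x)
  x <- unlist(x, use.names = FALSE)
  if (length(x) != 4L) stop("corners must have four elements c1..c4", call. = FALSE)
  ph_corners(x[1], x[2], x[3], x[4])
}

#' Noncompetitive lactate growth suppression
#'
#' Multiplicative growth penalty `Ki / (Ki + L)` applied to lactate-inhibited
#' groups; `Ki` is the lactate concentration at which growth is suppressed by
#' 50%.
#'
#' @param L ambient lactate concentration, mM (vectorised, `>= 0`).
#' @param Ki inhibition constant, mM (`> 0`).
#' @return Dimensionless factor(s) in `(0, 1]`, strictly decreasing in `L`.
#' @examples
#' lactate_suppression(15, Ki = 15)  # 0.5
#' @export
lactate_suppression <- function(L, Ki) {
  if (any(!is.finite(L)) || any(L < 0))
    stop("lactate concentration must be finite and >= 0", call. = FALSE)
  if (!is.finite(Ki) || Ki <= 0)
    stop("Ki must be finite and > 0", call. = FALSE)
  Ki / (Ki + L)
}

#' Monod saturation term
#'
#' `S / (Ks + S)`: zero at `S = 0`, one half at `S = Ks`, approaching one as
#' the substrate saturates.
#'
#' @param S substrate concentration (vectorised, `>= 0`), any unit.
#' @param Ks half-saturation constant, same unit as `S` (`> 0`).
#' @return Dimensionless factor(s) in `[0, 1)`.
#' @export
monod_term <- function(S, Ks) {
  if (any(!is.finite(S)) || any(S < 0))
    stop("substrate concentration must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(Ks)) || any(Ks <= 0))
    stop("Ks must be finite and > 0", call. = FALSE)
  S / (Ks + S)
}

#' Lactate inhibition regime
#'
#' Which functional groups receive the lactate suppression factor depends on
#' pH. Under the `"full"` regime only M1 is inhibited at mildly alkaline pH
#' (above the gate), while below the gate every group except M4 (the lactate
#' producers) is inhibited. `"lub_exempt"` additionally exempts the lactate
#' utilizers M7 and M8; `"none"` disables inhibition entirely.
#'
#' @param mode one of `"full"`, `"lub_exempt"`, `"none"`.
#' @param ph_gate pH below which the broad (all-but-M4) inhibition applies;
#'   default 6.0, between the two experimental set-points 5.5 and 6.5.
#' @return An object of class `inhibition_regime`.
#' @export
inhibition_regime <- function(mode = c("full", "lub_exempt", "none"),
                              ph_gate = 6.0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(ph_gate), length(ph_gate) == 1L)
  structure(list(mode = mode, ph_gate = ph_gate), class = "inhibition_regime")
}

#' Groups inhibited by lactate at a given pH
#'
#' @param regime an [inhibition_regime()].
#' @param pH scenario pH set-point.
#' @return Character vector of MFG ids subject to suppression.
#' @export
inhibited_mfgs <- function(regime, pH) {
  stopifnot(inherits(regime, "inhibition_regime"))
  if (regime$mode == "none") return(character(0))
  ids <- if (pH >= regime$ph_gate) "M1"
         else paste0("M", c(1, 2, 3, 5, 6, 7, 8, 9, 10))
  if (regime$mode == "lub_exempt") ids <- setdiff(ids, c("M7", "M8"))
  ids
}

#' Per-pathway specific growth rates of one strain
#'
#' For each pathway, mu = mu_max x min(Monod over substrates) x pH factor
#' x lactate suppression. The three factors multiply, so their order is
#' immaterial; a pathway with co-substrates (e.g. acetate for the butyrate
#' producers) is limited by its scarcest substrate.
#'
#' @param strain a strain row as produced by [generate_ensemble()] (a list
#'   with `ph_corners`, and per-pathway `mu_max`, `Ks` and substrate names).
#' @param concentrations named numeric vector of resource concentrations in
#'   their native units.
#' @param regime an [inhibition_regime()].
#' @param pH scenario pH.
#' @return Named numeric vector of specific growth rates (day^-1), one per
#'   pathway; the strain's total growth rate is their sum.
#' @export
strain_growth_rate <- function(strain, concentrations, regime, pH) {
  inhib <- strain$mfg %in% inhibited_mfgs(regime, pH)
  L <- max(concentrations[["lactate"]], 0)
  supp <- if (inhib && !is.na(strain$Ki)) lactate_suppression(L, strain$Ki) else 1
  phf <- ph_growth_factor(pH, strain$ph_corners)
  vapply(strain$pathways, function(pw) {
    subs <- names(pw$substrates)
    mon <- min(vapply(seq_along(subs), function(i) {
      monod_term(max(concentrations[[subs[i]]], 0), pw$Ks[[i]])
    }, numeric(1)))
    pw$mu_max * mon * phf * supp
  }, numeric(1))
}
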