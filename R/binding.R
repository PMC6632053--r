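# Equilibrium binding models for fluorescence-anisotropy titrations.
#
# All concentrations are handled internally in nM; unit conversion happens at
# I/O boundaries only. Assay constants default to the competitive FP setup:
# tracer Kd1 = 13.0 nM, tracer at 50 nM, protein at 250 nM.

#' Bound-tracer fraction for a direct 1:1 titration
#'
#' Solves the quadratic mass balance for a single labeled ligand L binding a
#' protein P with dissociation constant `Kd`, and returns the bound fraction
#' \[PL\]/Lt. The numerically stable form
#' \deqn{f = 2 P_t / (S + \sqrt{S^2 - 4 L_t P_t}), \quad S = K_d + L_t + P_t}
#' avoids cancellation for tight binders.
#'
#' @param kd Dissociation constant (nM), `>= 0`.
#' @param lt Total labeled-ligand concentration (nM), `> 0`.
#' @param pt Total protein concentration (nM), `>= 0`. Vectorized.
#' @return Bound fraction in `[0, 1]`, same length as the recycled inputs.
#' @examples
#' frac_bound_direct(13.0, 50, 250)   # ~0.94 at the assay constants
#' @export
frac_bound_direct <- function(kd, lt, pt) {
  if (any(lt <= 0)) stop("`lt` must be > 0", call. = FALSE)
  if (any(kd < 0) || any(pt < 0)) {
    stop("`kd` and `pt` must be non-negative", call. = FALSE)
  }
  s <- kd + lt + pt
  disc <- s * s - 4 * lt * pt
  disc[disc < 0] <- 0  # round-off guard; exact disc >= (kd)^2 >= 0
  f <- 2 * pt / (s + sqrt(disc))
  pmin(pmax(f, 0), 1)
}

#' Anisotropy of a direct 1:1 titration
#'
#' Linear map of the bound fraction onto the anisotropy scale:
#' `r = r0 + (rb - r0) * frac_bound_direct(kd, lt, pt)`.
#'
#' @param r0 Anisotropy of the free labeled peptide.
#' @param rb Anisotropy of the protein-tracer complex. `rb >= r0` is expected
#'   for a mass-gaining complex; a violation is flagged with a warning, not an
#'   error, so that fitted parameters can be inspected.
#' @inheritParams frac_bound_direct
#' @return Anisotropy values.
#' @export
anisotropy_direct <- function(r0, rb, kd, lt, pt) {
  if (any(rb < r0)) {
    warning("rb < r0: complex anisotropy below free-tracer anisotropy",
            call. = FALSE)
  }
  r0 + (rb - r0) * frac_bound_direct(kd, lt, pt)
}

#' Cubic intermediates of the exact two-ligand competition solution
#'
#' The free-protein concentration `p` in a system where a labeled ligand
#' (Kd1, total `lst`) and an unlabeled competitor (Kd2, total `lt`) compete
#' for one site on a protein (total `pt`) is the physical root of
#' \deqn{p^3 + d p^2 + e p + f = 0}
#' with
#' \deqn{d = K_{d1} + K_{d2} + L_{st} + L_t - P_t}
#' \deqn{e = K_{d1}(L_t - P_t) + K_{d2}(L_{st} - P_t) + K_{d1} K_{d2}}
#' \deqn{f = -K_{d1} K_{d2} P_t}
#' and the trigonometric angle
#' \deqn{\theta = \arccos\frac{-2 d^3 + 9 d e - 27 f}{2\sqrt{(d^2 - 3e)^3}}.}
#'
#' @param kd1,kd2 Tracer and competitor dissociation constants (nM), `> 0`.
#' @param lst,lt Total labeled and unlabeled ligand concentrations (nM).
#' @param pt Total protein concentration (nM).
#' @return A list with components `d`, `e`, `f`, `theta` and the discriminant
#'   term `q = d^2 - 3 e` (all scalars).
#' @export
competition_intermediates <- function(kd1, kd2, lst, lt, pt) {
  d <- kd1 + kd2 + lst + lt - pt
  e <- kd1 * (lt - pt) + kd2 * (lst - pt) + kd1 * kd2
  f <- -kd1 * kd2 * pt
  q <- d * d - 3 * e
  if (q < 0) {
    if (q > -1e-9 * max(d * d, 1)) q <- 0
    else stop("negative discriminant d^2 - 3e: invalid competition inputs",
              call. = FALSE)
  }
  theta <- if (q == 0) 0 else {
    arg <- (-2 * d^3 + 9 * d * e - 27 * f) / (2 * sqrt(q)^3)
    if (arg > 1 || arg < -1) {
      if (abs(arg) - 1 > 1e-9) {
        stop(sprintf(paste0(
          "arccos argument %.6g outside [-1, 1] beyond tolerance ",
          "(d = %.6g, e = %.6g, f = %.6g)"), arg, d, e, f), call. = FALSE)
      }
      arg <- max(min(arg, 1), -1)
    }
    acos(arg)
  }
  list(d = d, e = e, f = f, q = q, theta = theta)
}

# Physical free-protein root of the competition cubic, closed form.
# When the physical root is much smaller than |d| the direct trigonometric
# expression loses precision by cancellation; it is then re-derived from the
# two well-conditioned roots through Vieta's product r1*r2*r3 = -f.
.free_protein_closed <- function(kd1, kd2, lst, lt, pt) {
  if (pt == 0) return(0)
  ci <- competition_intermediates(kd1, kd2, lst, lt, pt)
  if (ci$q == 0) return(max(-ci$d / 3, 0))
  sq <- sqrt(ci$q)
  roots <- (2 * sq * cos((ci$theta + 2 * pi * c(0, 1, 2)) / 3) - ci$d) / 3
  # The trigonometric roots lose precision when the physical root is much
  # smaller than |d| (cancellation) or when theta approaches 0/pi (angle
  # sensitivity). Deflating the well-conditioned dominant root and solving
  # the remaining quadratic (stable form, Vieta for the small root) adds
  # accurate candidates for those regimes.
  cand <- roots
  r1 <- roots[which.max(abs(roots))]
  if (is.finite(r1) && abs(r1) > 0) {
    b <- ci$d + r1
    cc <- -ci$f / r1
    disc <- b * b - 4 * cc
    if (is.finite(disc) && disc >= 0) {
      sqd <- sqrt(disc)
      qq <- -(b + sign(b) * sqd) / 2
      cand <- c(cand, if (qq != 0) c(qq, cc / qq) else c(-b, 0))
    }
  }
  # physical root: the candidate satisfying the protein mass balance
  g <- function(p) p + lst * p / (p + kd1) + lt * p / (p + kd2) - pt
  clamped <- pmin(pmax(cand, 0), pt)
  p <- clamped[which.min(abs(vapply(clamped, g, numeric(1))))]
  # Newton polish on the cubic itself (Horner form) for the last digits
  for (it in 1:3) {
    val <- ((p + ci$d) * p + ci$e) * p + ci$f
    der <- (3 * p + 2 * ci$d) * p + ci$e
    if (!is.finite(der) || abs(der) < 1e-300) break
    p_new <- p - val / der
    if (!is.finite(p_new) || p_new < 0 || p_new > pt) break
    p <- p_new
  }
  min(max(p, 0), pt)
}

#' Bound-tracer fraction under competitive displacement (exact closed form)
#'
#' Evaluates the exact closed-form solution of the two-ligand, one-site
#' equilibrium (trigonometric solution of the cubic in free protein, see
#' [competition_intermediates()]) and returns the bound fraction of the
#' labeled ligand, `p / (p + kd1)`.
#'
#' The standard assay validity condition is `pt > lst` (otherwise free tracer
#' dominates the signal); a violation raises a warning, not an error, so the
#' model remains usable for diagnostics.
#'
#' @inheritParams competition_intermediates
#' @param validate Warn when `pt <= lst`? Default `TRUE`.
#' @return Bound fraction of the labeled ligand in `[0, 1]`. Vectorized over
#'   `lt` (and any other argument by recycling).
#' @seealso [solve_equilibrium_numeric()] for the independent numerical
#'   mass-balance solver used to certify this closed form.
#' @examples
#' # with no competitor the model reduces to the direct 1:1 quadratic
#' frac_bound_competition(13.0, 18.6, 50, 0, 250)
#' frac_bound_direct(13.0, 50, 250)
#' @export
frac_bound_competition <- function(kd1, kd2, lst, lt, pt, validate = TRUE) {
  m <- cbind(kd1, kd2, lst, lt, pt)
  if (any(m < 0)) stop("concentrations and Kd values must be >= 0",
                       call. = FALSE)
  if (any(m[, 1] <= 0) || any(m[, 2] <= 0)) {
    stop("`kd1` and `kd2` must be > 0", call. = FALSE)
  }
  if (validate && any(m[, 5] <= m[, 3] & m[, 5] > 0)) {
    warning("validity condition pt > lst violated", call. = FALSE)
  }
  vapply(seq_len(nrow(m)), function(i) {
    p <- .free_protein_closed(m[i, 1], m[i, 2], m[i, 3], m[i, 4], m[i, 5])
    p / (p + m[i, 1])
  }, numeric(1))
}

#' Anisotropy under competitive displacement
#'
#' @inheritParams anisotropy_direct
#' @inheritParams frac_bound_competition
#' @return Anisotropy values, vectorized over `lt`.
#' @export
anisotropy_competition <- function(r0, rb, kd1, kd2, lst, lt, pt,
                                   validate = TRUE) {
  r0 + (rb - r0) * frac_bound_competition(kd1, kd2, lst, lt, pt,
                                          validate = validate)
}

#' Numerical two-ligand equilibrium solver (independent oracle)
#'
#' Solves the coupled mass-action system
#' \deqn{[P][L^*]/[PL^*] = K_{d1}, \quad [P][L]/[PL] = K_{d2}}
#' with conservation of all three totals, by bracketed root-finding on the
#' free-protein concentration over `[0, pt]` followed by Newton polishing.
#' This routine shares no code with the closed-form solution and serves as
#' its independent certification oracle.
#'
#' @inheritParams competition_intermediates
#' @return Named numeric vector `c(bound_tracer =, bound_competitor =)` (nM).
#'   The residual of the protein mass balance is guaranteed `<= 1e-9 * pt`.
#' @export
solve_equilibrium_numeric <- function(kd1, kd2, lst, lt, pt) {
  if (any(c(kd1, kd2) <= 0) || any(c(lst, lt, pt) < 0)) {
    stop("invalid equilibrium inputs", call. = FALSE)
  }
  if (pt == 0) return(c(bound_tracer = 0, bound_competitor = 0))
  g <- function(p) p + lst * p / (p + kd1) + lt * p / (p + kd2) - pt
  p <- stats::uniroot(g, c(0, pt), tol = 1e-13 * max(pt, 1))$root
  for (i in 1:4) {  # Newton polish toward machine precision
    gp <- 1 + lst * kd1 / (p + kd1)^2 + lt * kd2 / (p + kd2)^2
    step <- g(p) / gp
    p <- min(max(p - step, 0), pt)
  }
  if (abs(g(p)) > 1e-9 * pt) {
    stop(sprintf(
      "equilibrium residual %.3g exceeds 1e-9 * pt (kd1=%g kd2=%g lst=%g lt=%g pt=%g)",
      abs(g(p)), kd1, kd2, lst, lt, pt), call. = FALSE)
  }
  c(bound_tracer = lst * p / (p + kd1),
    bound_competitor = lt * p / (p + kd2))
}
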