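# --- shared fitting machinery ------------------------------------------------

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

# additive-logistic transform for a 2-parameter simplex slice (p0, p1)
.simplex2 <- function(a, b) {
  ea <- exp(a); eb <- exp(b)
  s <- 1 + ea + eb
  c(ea / s, eb / s)
}

# bounded quasi-Newton on transformed parameters with optional random restarts
.fit_ml <- function(objfn, start, lower = -Inf, upper = Inf, restarts = 2L) {
  safe <- function(par) {
    v <- tryCatch(objfn(par), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  best <- nlminb(start, safe, lower = lower, upper = upper,
                 control = list(iter.max = 1000L, eval.max = 3000L,
                                rel.tol = 1e-10))
  tries <- 0L
  while (best$convergence != 0L && tries < restarts) {
    tries <- tries + 1L
    jitter <- start + rnorm(length(start), sd = 0.5)
    jitter <- pmin(pmax(jitter, lower + 1e-6), upper - 1e-6)
    alt <- nlminb(jitter, safe, lower = lower, upper = upper,
                  control = list(iter.max = 1000L, eval.max = 3000L,
                                 rel.tol = 1e-10))
    if (alt$objective < best$objective) best <- alt
  }
  list(par = best$par, objective = best$objective,
       converged = best$convergence == 0L || best$objective < 1e9,
       n_iter = best$iterations)
}

.fit_result <- function(model, lnL, params, fixed, opt, og_id = NA_character_,
                        np = NA_integer_, flags = character(0)) {
  structure(list(model = model, lnL = lnL, params = params, fixed = fixed,
                 converged = opt$converged, n_iter = opt$n_iter,
                 og_id = og_id, np = np, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit [", x$model, "] lnL =", format(x$lnL, digits = 10),
      if (!x$converged) "(NOT CONVERGED)", "\n")
  pp <- unlist(x$params)
  cat(paste0("  ", names(pp), " = ", signif(pp, 5), collapse = "\n"), "\n")
  invisible(x)
}

#' Cap dN/dS estimates for reporting
#'
#' Estimates outside `[0.01, 10]` are reported at the cap; stored maximum
#' likelihood estimates are never modified.
#'
#' @param omega Numeric vector of dN/dS values.
#' @param lower,upper Reporting caps (defaults 0.01 and 10).
#' @return The capped vector.
#' @export
cap_omega <- function(omega, lower = 0.01, upper = 10) {
  pmin(pmax(omega, lower), upper)
}

# resolve the orthogroup pieces every fit needs
.fit_inputs <- function(og, pi = NULL) {
  stopifnot(inherits(og, "orthogroup"))
  if (is.null(pi)) pi <- estimate_f3x4(og$alignment)
  states <- as_state_matrix(og$alignment)
  pat <- .site_patterns(states)
  list(og = og, pi = pi, pat = pat, cache = new.env(parent = emptyenv()))
}

.mix_loglik <- function(cl, props, weights) {
  keep <- props > 0
  lw <- sweep(cl[, keep, drop = FALSE], 2L, log(props[keep]), `+`)
  mx <- apply(lw, 1L, max)
  sum(weights * (mx + log(rowSums(exp(lw - mx)))))
}

# evaluate a model spec on precomputed inputs
.eval_model <- function(inp, lt, model, scale) {
  if (identical(model$sharing, "branch")) {
    site_ll <- .branch_mix_loglik(inp$pat$states, lt$tree, lt$branch_labels,
                                  model, scale, inp$cache)
    return(sum(inp$pat$weights * site_ll))
  }
  cl <- .class_site_loglik(inp$pat$states, lt$tree, lt$branch_labels, model,
                           scale, inp$cache)
  props <- vapply(model$classes, `[[`, numeric(1), "prop")
  .mix_loglik(cl, props, inp$pat$weights)
}

# --- single-omega and branch models -----------------------------------------

#' Fit the single-omega (M0) codon model
#'
#' Maximum-likelihood estimates of kappa, a single dN/dS shared by every
#' branch, and a global branch-length scale that converts the orthogroup
#' tree's lengths into expected substitutions per codon. Initial values are
#' kappa = 2 and omega = 0.001. The estimated scale is reused (held fixed) by
#' the branch, branch-site and selection-intensity fits.
#'
#' @param og An [orthogroup()].
#' @param pi Equilibrium codon frequencies; default F3x4 from the alignment.
#' @param init_omega,init_kappa Optimiser starting values.
#' @return A `fit_result` with `params$kappa`, `params$omega`,
#'   `params$scale`.
#' @export
fit_single_omega <- function(og, pi = NULL, init_omega = 0.001,
                             init_kappa = 2) {
  inp <- .fit_inputs(og, pi)
  lt <- og$tree
  obj <- function(par) {
    -.eval_model(inp, lt, model_m0(exp(par[1]), exp(par[2]), inp$pi),
                 exp(par[3]))
  }
  opt <- .fit_ml(obj, c(log(init_kappa), log(init_omega), 0),
                 lower = c(log(1e-3), log(1e-6), log(1e-4)),
                 upper = c(log(100), log(100), log(1e3)))
  est <- exp(opt$par)
  .fit_result("m0", -opt$objective,
              params = list(kappa = est[1], omega = est[2], scale = est[3],
                            omega_reported = cap_omega(est[2])),
              fixed = list(pi = inp$pi), opt, og$og_id, np = 3L)
}

#' Fit the branch model with one dN/dS per trait state
#'
#' Terminal branches to reduced-state and absent-state tips form their own
#' partitions; all other branches (including internal ones) are background.
#' The branch-length scale is taken from a single-omega fit and held fixed;
#' kappa and the per-partition dN/dS values are estimated.
#'
#' @param og An [orthogroup()] whose tree carries three-state labels.
#' @param m0 Optional `fit_result` of [fit_single_omega()]; computed if
#'   missing.
#' @param require_all_states If `TRUE` (default) the orthogroup is skipped
#'   (with `ok = FALSE`, reason `"missing_partition"`) unless all three
#'   bristle states are represented.
#' @param pi Equilibrium codon frequencies; default F3x4.
#' @return A `fit_result` with `params$omega` named by partition
#'   (`present`/`reduced`/`absent`), or a skip record.
#' @export
fit_branch_three_omega <- function(og, m0 = NULL, require_all_states = TRUE,
                                   pi = NULL) {
  inp <- .fit_inputs(og, pi)
  lt <- og$tree
  parts <- sort(unique(lt$branch_labels))
  if (require_all_states && !all(0:2 %in% parts)) {
    return(list(ok = FALSE, reason = "missing_partition", og_id = og$og_id))
  }
  if (is.null(m0)) m0 <- fit_single_omega(og, pi = inp$pi)
  scale <- m0$params$scale
  np <- length(parts)
  obj <- function(par) {
    om <- setNames(exp(par[-1]), as.character(parts))
    -.eval_model(inp, lt, model_branch(exp(par[1]), om, inp$pi), scale)
  }
  opt <- .fit_ml(obj, c(log(m0$params$kappa), rep(log(max(m0$params$omega, 1e-4)), np)),
                 lower = c(log(1e-3), rep(log(1e-6), np)),
                 upper = c(log(100), rep(log(100), np)))
  om <- setNames(exp(opt$par[-1]),
                 c("0" = "present", "1" = "reduced", "2" = "absent")[as.character(parts)])
  .fit_result("branch3", -opt$objective,
              params = list(kappa = exp(opt$par[1]), omega = om,
                            omega_reported = cap_omega(om)),
              fixed = list(pi = inp$pi, scale = scale), opt, og$og_id,
              np = 1L + np)
}

# --- branch-site model A -----------------------------------------------------

.fit_model_a_impl <- function(og, foreground, fix_w2, m0, pi, init = NULL) {
  inp <- .fit_inputs(og, pi)
  lt <- label_contrast(og$tree, foreground)
  if (!any(lt$branch_labels == 1L)) {
    return(list(ok = FALSE, reason = "no_foreground_branch", og_id = og$og_id))
  }
  if (is.null(m0)) m0 <- fit_single_omega(og, pi = inp$pi)
  scale <- m0$params$scale
  build <- function(par) {
    p <- .simplex2(par[3], par[4])
    w2 <- if (fix_w2) 1 else 1 + exp(par[5])
    model_a(exp(par[1]), .inv_logit(par[2]), w2, p[1], p[2], inp$pi)
  }
  obj <- function(par) -.eval_model(inp, lt, build(par), scale)
  if (inherits(init, "fit_result") && !is.null(init$params$w0)) {
    ip <- init$params
    p2 <- max(1 - ip$p0 - ip$p1, 1e-8)
    start <- c(log(ip$kappa), .logit(min(max(ip$w0, 1e-6), 1 - 1e-6)),
               log(max(ip$p0, 1e-8) / p2), log(max(ip$p1, 1e-8) / p2))
  } else {
    w0_init <- min(max(m0$params$omega, 1e-3), 0.9)
    start <- c(log(m0$params$kappa), .logit(w0_init), .logit(0.45) - log(0.1),
               .logit(0.45) - log(0.1))
  }
  lower <- c(log(1e-3), -15, -15, -15)
  upper <- c(log(100), 15, 15, 15)
  if (!fix_w2) {
    # never start w2 against the boundary: the log(w2 - 1) transform has a
    # vanishing gradient there and would pin the fit at the null
    w2_init <- if (inherits(init, "fit_result") && !is.null(init$params$w2) &&
                   init$params$w2 > 1.05) {
      init$params$w2
    } else 1.5
    start <- c(start, log(w2_init - 1))
    lower <- c(lower, -30)
    upper <- c(upper, log(50))
  }
  start <- pmin(pmax(start, lower), upper)
  opt <- .fit_ml(obj, start, lower, upper)
  p <- .simplex2(opt$par[3], opt$par[4])
  w2 <- if (fix_w2) 1 else 1 + exp(opt$par[5])
  .fit_result(if (fix_w2) "modelAnull" else "modelA", -opt$objective,
              params = list(kappa = exp(opt$par[1]),
                            w0 = .inv_logit(opt$par[2]), w2 = w2,
                            p0 = p[1], p1 = p[2]),
              fixed = list(pi = inp$pi, scale = scale, foreground = foreground),
              opt, og$og_id, np = if (fix_w2) 4L else 5L)
}

#' Fit branch-site model A
#'
#' Mixture of four site classes (0, 1, 2a, 2b); classes 2a/2b allow
#' `w2 >= 1` on the foreground partition only. Compared with
#' [fit_model_a_null()] by a likelihood-ratio test for evidence of positive
#' selection on foreground branches.
#'
#' @param og An [orthogroup()].
#' @param foreground `"absent"` or `"reduced"`: the tip state whose terminal
#'   branches form the foreground partition.
#' @param m0 Optional single-omega `fit_result` supplying the fixed
#'   branch-length scale.
#' @param pi Equilibrium codon frequencies; default F3x4.
#' @param init Optional `fit_result` (e.g. the null fit) used as warm start.
#' @return A `fit_result` with `w0`, `w2`, `p0`, `p1`, `kappa`.
#' @export
fit_model_a <- function(og, foreground = c("absent", "reduced"), m0 = NULL,
                        pi = NULL, init = NULL) {
  .fit_model_a_impl(og, match.arg(foreground), fix_w2 = FALSE, m0, pi, init)
}

#' Fit the branch-site null model (A_null, w2 fixed at 1)
#'
#' @inheritParams fit_model_a
#' @return A `fit_result`; free parameters are kappa, `w0`, `p0`, `p1`.
#' @export
fit_model_a_null <- function(og, foreground = c("absent", "reduced"),
                             m0 = NULL, pi = NULL, init = NULL) {
  .fit_model_a_impl(og, match.arg(foreground), fix_w2 = TRUE, m0, pi, init)
}

#' Empirical-Bayes site posteriors under a fitted branch-site model
#'
#' Evaluates, at the maximum-likelihood estimates, the posterior probability
#' of each site class for every codon site
#' (`P(c | data) propto prop_c L_site(c)`), and flags sites whose combined
#' posterior for the positively selected classes (2a + 2b) exceeds the
#' threshold. This is naive empirical Bayes at the MLEs (no integration over
#' parameter uncertainty).
#'
#' @param og The [orthogroup()] used for the fit.
#' @param fit A `fit_result` from [fit_model_a()].
#' @param threshold Posterior threshold for flagging (default 0.95).
#' @return A list with `posterior` (sites x classes matrix, columns
#'   `0`, `1`, `2a`, `2b`) and `flagged` (integer site indices).
#' @export
site_posteriors <- function(og, fit, threshold = 0.95) {
  stopifnot(inherits(fit, "fit_result"), fit$model %in% c("modelA", "modelAnull"))
  pr <- fit$params
  model <- model_a(pr$kappa, pr$w0, pr$w2, pr$p0, pr$p1, fit$fixed$pi)
  lt <- label_contrast(og$tree, fit$fixed$foreground)
  full <- .log_likelihood_full(og$alignment, lt, model, fit$fixed$scale)
  props <- full$props
  lw <- sweep(full$class_loglik, 2L, log(pmax(props, 1e-300)), `+`)
  mx <- apply(lw, 1L, max)
  post <- exp(lw - mx)
  post <- post / rowSums(post)
  post <- post[full$pattern_map, , drop = FALSE]
  colnames(post) <- c("0", "1", "2a", "2b")
  flagged <- which(post[, "2a"] + post[, "2b"] > threshold)
  list(posterior = post, flagged = flagged)
}

# --- RELAX-style selection-intensity models ---------------------------------

# parameter block: u, v, s >= 0 give w1 = exp(-u), w0 = exp(-u - v),
# w2 = exp(s); a, b give proportions via the additive-logistic map
.relax_omegas <- function(u, v, s) c(exp(-u - v), exp(-u), exp(s))

.relax_props <- function(a, b) {
  p <- .simplex2(a, b)
  c(p[1], p[2], 1 - p[1] - p[2])
}

# inverse transforms, used for warm starts
.relax_omega_pars <- function(w) {
  w <- pmin(pmax(w, 1e-6), c(1 - 1e-9, 1 - 1e-9, Inf))
  u <- -log(w[2]); v <- -log(w[1]) - u; s <- log(max(w[3], 1))
  c(max(u, 0), max(v, 0), min(max(s, 0), 15))
}

.relax_prop_pars <- function(p) {
  p <- pmax(p, 1e-8); p <- p / sum(p)
  c(log(p[1] / p[3]), log(p[2] / p[3]))
}

.k_bounds <- c(1e-3, 50)

.fit_relax_impl <- function(og, test, fix_k, m0, pi, init = NULL) {
  inp <- .fit_inputs(og, pi)
  lt <- label_contrast(og$tree, test)
  if (!any(lt$branch_labels == 1L)) {
    return(list(ok = FALSE, reason = "no_test_branch", og_id = og$og_id))
  }
  if (is.null(m0)) m0 <- fit_single_omega(og, pi = inp$pi)
  scale <- m0$params$scale
  free_k <- is.null(fix_k)
  build <- function(par) {
    w <- .relax_omegas(par[2], par[3], par[4])
    p <- .relax_props(par[5], par[6])
    k <- if (free_k) exp(par[7]) else fix_k
    model_relax(exp(par[1]), w, p, k, inp$pi)
  }
  obj <- function(par) -.eval_model(inp, lt, build(par), scale)
  base_cold <- c(log(m0$params$kappa), log(2), log(10), log(1.5),
                 .logit(0.5) - log(0.2), .logit(0.4) - log(0.2))
  base_warm <- if (inherits(init, "fit_result") && !is.null(init$params$omega) &&
                   length(init$params$omega) == 3L) {
    c(log(init$params$kappa),
      .relax_omega_pars(init$params$omega),
      .relax_prop_pars(init$params$prop))
  } else NULL
  lower <- c(log(1e-3), 0, 0, 0, -15, -15)
  upper <- c(log(100), 15, 15, log(50), 15, 15)
  if (free_k) {
    k0 <- if (inherits(init, "fit_result") && !is.null(init$params$k)) {
      min(max(init$params$k, .k_bounds[1] * 2), .k_bounds[2] / 2)
    } else 1
    lower <- c(lower, log(.k_bounds[1]))
    upper <- c(upper, log(.k_bounds[2]))
    # the k surface can be multimodal (a mirror-image mode with degenerate
    # categories and k on the wrong side of 1); fit from both the warm start
    # and the generic start and keep the better optimum
    starts <- list(c(base_cold, 0))
    if (!is.null(base_warm)) starts <- c(list(c(base_warm, log(k0))), starts)
  } else {
    starts <- list(if (is.null(base_warm)) base_cold else base_warm)
  }
  opt <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    cand <- .fit_ml(obj, s, lower, upper)
    if (is.null(opt) || cand$objective < opt$objective) opt <- cand
  }
  w <- .relax_omegas(opt$par[2], opt$par[3], opt$par[4])
  p <- .relax_props(opt$par[5], opt$par[6])
  k <- if (free_k) exp(opt$par[7]) else fix_k
  flags <- character(0)
  if (free_k && (k <= .k_bounds[1] * 1.01 || k >= .k_bounds[2] * 0.99)) {
    flags <- "k_at_bound"
  }
  .fit_result(if (free_k) "relax" else "relaxnull", -opt$objective,
              params = list(kappa = exp(opt$par[1]), omega = w, prop = p,
                            k = k),
              fixed = list(pi = inp$pi, scale = scale, test = test),
              opt, og$og_id, np = if (free_k) 7L else 6L, flags = flags)
}

#' Fit the selection-intensity (RELAX-style) model
#'
#' Three shared dN/dS categories (`w0 <= w1 <= 1 <= w2`) whose values on test
#' branches are raised to the exponent `k`; `fix_k = 1` gives the null model
#' for the likelihood-ratio test (df = 1). `k` is bounded to `[1e-3, 50]`;
#' fits hitting a bound are flagged `"k_at_bound"`.
#'
#' @param og An [orthogroup()].
#' @param test `"absent"` or `"reduced"`: the tip state whose terminal
#'   branches are the test partition (reference = bristles present).
#' @param fix_k Optional fixed value of `k` (use 1 for the null model).
#' @param m0 Optional single-omega `fit_result` supplying the fixed scale.
#' @param pi Equilibrium codon frequencies; default F3x4.
#' @param init Optional `fit_result` of a nested fit (e.g. the `fix_k = 1`
#'   null) used as a warm start.
#' @return A `fit_result` with `omega` (3 categories), `prop`, `k`, `kappa`.
#' @export
fit_relax <- function(og, test = c("absent", "reduced"), fix_k = NULL,
                      m0 = NULL, pi = NULL, init = NULL) {
  .fit_relax_impl(og, match.arg(test), fix_k, m0, pi, init)
}

#' Fit the partitioned descriptive model (PDM)
#'
#' Independent three-category dN/dS distributions (values and proportions)
#' for test and reference branches; used descriptively, no test attached.
#'
#' @inheritParams fit_relax
#' @param init Optional `fit_result` of [fit_relax()] used as a warm start
#'   (the test block starts at `omega^k`), which also guarantees the nesting
#'   `lnL(PDM) >= lnL(RELAX)` at the optimum.
#' @return A `fit_result` with `omega_ref`, `prop_ref`, `omega_test`,
#'   `prop_test`, `kappa`.
#' @export
fit_relax_pdm <- function(og, test = c("absent", "reduced"), m0 = NULL,
                          pi = NULL, init = NULL) {
  test <- match.arg(test)
  inp <- .fit_inputs(og, pi)
  lt <- label_contrast(og$tree, test)
  if (!any(lt$branch_labels == 1L)) {
    return(list(ok = FALSE, reason = "no_test_branch", og_id = og$og_id))
  }
  if (is.null(m0)) m0 <- fit_single_omega(og, pi = inp$pi)
  scale <- m0$params$scale
  build <- function(par) {
    wr <- .relax_omegas(par[2], par[3], par[4])
    pr <- .relax_props(par[5], par[6])
    wt <- .relax_omegas(par[7], par[8], par[9])
    pt <- .relax_props(par[10], par[11])
    model_pdm(exp(par[1]), wr, pr, wt, pt, inp$pi)
  }
  obj <- function(par) -.eval_model(inp, lt, build(par), scale)
  if (inherits(init, "fit_result") && !is.null(init$params$k)) {
    w <- init$params$omega; p <- init$params$prop; k <- init$params$k
    start <- c(log(init$params$kappa),
               .relax_omega_pars(w), .relax_prop_pars(p),
               .relax_omega_pars(w^k), .relax_prop_pars(p))
  } else {
    blk <- c(log(2), log(10), log(1.5), .logit(0.5) - log(0.2),
             .logit(0.4) - log(0.2))
    start <- c(log(m0$params$kappa), blk, blk)
  }
  lower <- c(log(1e-3), rep(c(0, 0, 0, -15, -15), 2))
  upper <- c(log(100), rep(c(15, 15, log(50), 15, 15), 2))
  start <- pmin(pmax(start, lower), upper)
  opt <- .fit_ml(obj, start, lower, upper)
  .fit_result("pdm", -opt$objective,
              params = list(kappa = exp(opt$par[1]),
                            omega_ref = .relax_omegas(opt$par[2], opt$par[3], opt$par[4]),
                            prop_ref = .relax_props(opt$par[5], opt$par[6]),
                            omega_test = .relax_omegas(opt$par[7], opt$par[8], opt$par[9]),
                            prop_test = .relax_props(opt$par[10], opt$par[11])),
              fixed = list(pi = inp$pi, scale = scale, test = test),
              opt, og$og_id, np = 11L)
}
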