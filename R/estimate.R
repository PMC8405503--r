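# ---- internal: design construction and likelihood machinery -----------------

# Gauss-Hermite nodes/weights (weight function exp(-x^2)), Golub-Welsch
.gauss_hermite <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  ev <- eigen(J, symmetric = TRUE)
  ord <- order(ev$values)
  list(x = ev$values[ord], w = sqrt(pi) * ev$vectors[1, ord]^2)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Build the per-subject design: response, times, dose superposition at the
# observation times, log weight ratio, daily TSH (if needed).  Everything
# that does not depend on the estimated parameters is computed once.
.build_design <- function(data, model, response = c("auto", "ft4_norm", "ft4")) {
  stopifnot(inherits(data, "ft4_dataset"), inherits(model, "ft4_model"))
  response <- match.arg(response)
  ob <- data$observations
  if (response == "auto")
    response <- if (!is.null(ob$ft4_norm)) "ft4_norm" else "ft4"
  if (is.null(ob[[response]]))
    stop("response column '", response, "' not present; run normalize_ft4()?")
  wref <- model$wref
  if (is.null(wref)) {
    wref <- stats::median(ob$weight, na.rm = TRUE)
    if (!is.finite(wref)) stop("cannot derive wref: no body weights in data")
  }
  need_tsh <- !is.null(model$feedback)
  ids <- unique(ob$subject_id)
  subjects <- list()
  for (id in ids) {
    rows <- ob[ob$subject_id == id, , drop = FALSE]
    use <- !is.na(rows[[response]])
    if (sum(use) < 1) next
    t_obs <- rows$t[use]
    y <- rows[[response]][use]
    horizon <- max(t_obs)
    # weight trajectory with fallback to the reference weight
    wr <- rows[!is.na(rows$weight), c("t", "weight")]
    wfun <- if (nrow(wr) >= 2) {
      interpolate_trajectory(wr$t, wr$weight)
    } else if (nrow(wr) == 1) {
      local({ w0 <- wr$weight[1]; function(t) rep(w0, length(t)) })
    } else {
      local({ w0 <- wref; function(t) rep(w0, length(t)) })
    }
    dr <- rows[!is.na(rows$dose_daily), c("t", "dose_daily")]
    regimen <- expand_regimen(dr$t, dr$dose_daily, horizon)
    sp <- .superpose(regimen, t_obs, model$ka, model$kel, model$F)
    tsh_daily <- NULL
    if (need_tsh) {
      tr <- rows[!is.na(rows$tsh), c("t", "tsh")]
      days <- seq(0, ceiling(horizon), by = 1)
      tsh_daily <- if (nrow(tr) >= 2) {
        interpolate_trajectory(tr$t, tr$tsh)(days)
      } else if (nrow(tr) == 1) {
        rep(tr$tsh[1], length(days))
      } else {
        rep(3, length(days))  # mid-target fallback when TSH is absent
      }
    }
    subjects[[id]] <- list(id = id, y = y, t = t_obs, S = sp$A_C,
                           logw = log(wfun(t_obs) / wref),
                           weight_fun = wfun, regimen = regimen,
                           tsh_daily = tsh_daily, horizon = horizon)
  }
  if (!length(subjects)) stop("no usable observations")
  n_obs <- vapply(subjects, function(s) length(s$y), integer(1))
  idx <- rep(seq_along(subjects), n_obs)
  list(subjects = subjects, wref = wref, response = response,
       idx = idx, n = length(subjects), n_obs = n_obs,
       y = unlist(lapply(subjects, `[[`, "y"), use.names = FALSE),
       t = unlist(lapply(subjects, `[[`, "t"), use.names = FALSE),
       S = unlist(lapply(subjects, `[[`, "S"), use.names = FALSE),
       logw = unlist(lapply(subjects, `[[`, "logw"), use.names = FALSE))
}

# Endogenous-production channels at the observation times, stacked across
# subjects.  Returns list(base, extra):
#   prediction numerator P = kendo_i * base + extra + S
# For no feedback: base = 1/kel, extra = 0.
# categorical:   base = 1/kel, extra = sum_m betas[m] * conv(indicator_m)
# additive:      base = 1/kel, extra = beta3 * conv(f(TSH))
# multiplicative: base = conv(f(TSH)), extra = 0
.endo_channels <- function(design, model) {
  fb <- model$feedback
  kel <- model$kel
  nobs_total <- length(design$y)
  if (is.null(fb))
    return(list(base = rep(1 / kel, nobs_total), extra = numeric(nobs_total)))
  base <- numeric(0); extra <- numeric(0)
  for (s in design$subjects) {
    tshd <- pmax(s$tsh_daily, .tsh_floor)
    if (fb$coupling == "categorical") {
      cats <- tsh_category(tshd, fb$scheme)
      ex <- numeric(length(s$t))
      for (m in seq_along(fb$betas)) {
        ind <- as.numeric(cats == m + 1)
        ex <- ex + fb$betas[m] * .endo_response(ind, kel, s$t)
      }
      base <- c(base, rep(1 / kel, length(s$t)))
      extra <- c(extra, ex)
    } else {
      fch <- .endo_response(.f_tsh(tshd, fb), kel, s$t)
      if (fb$coupling == "multiplicative") {
        base <- c(base, fch)
        extra <- c(extra, numeric(length(s$t)))
      } else {  # additive
        base <- c(base, rep(1 / kel, length(s$t)))
        extra <- c(extra, fb$betas[1] * fch)
      }
    }
  }
  list(base = base, extra = extra)
}

# Stacked per-subject objective and analytic gradient of the penalized
# (conditional) negative log-likelihood, as functions of the eta matrix.
# eta: n x 3 matrix (kendo, fV, betaW); only `active` columns vary.
.inner_obj <- function(eta, design, model, chan) {
  idx <- design$idx
  b <- model$sigma_prop
  kendo_i <- model$kendo * exp(eta[, 1])
  fV_i <- model$fV * exp(eta[, 2])
  bW_i <- model$betaW * exp(eta[, 3])
  P <- kendo_i[idx] * chan$base + chan$extra + design$S
  V <- fV_i[idx] * exp(bW_i[idx] * design$logw)
  c_pred <- 0.3 * P / V
  bad <- !is.finite(c_pred) | c_pred <= 0
  obj_obs <- rep(Inf, length(c_pred))
  ok <- !bad
  r <- design$y[ok] - c_pred[ok]
  obj_obs[ok] <- log(b * c_pred[ok]) + r^2 / (2 * b^2 * c_pred[ok]^2) +
    0.5 * log(2 * pi)
  g <- as.numeric(rowsum(obj_obs, idx, reorder = FALSE))
  om <- model$omega
  for (k in 1:3) if (om[k] > 0)
    g <- g + 0.5 * eta[, k]^2 / om[k]^2 + log(om[k]) + 0.5 * log(2 * pi)
  list(g = g, c_pred = c_pred, P = P)
}

.inner_grad <- function(eta, design, model, chan) {
  idx <- design$idx
  b <- model$sigma_prop
  kendo_i <- model$kendo * exp(eta[, 1])
  fV_i <- model$fV * exp(eta[, 2])
  bW_i <- model$betaW * exp(eta[, 3])
  P <- kendo_i[idx] * chan$base + chan$extra + design$S
  V <- fV_i[idx] * exp(bW_i[idx] * design$logw)
  c_pred <- 0.3 * P / V
  if (any(!is.finite(c_pred) | c_pred <= 0)) return(NULL)
  r <- design$y - c_pred
  dgdc <- 1 / c_pred - r / (b^2 * c_pred^2) - r^2 / (b^2 * c_pred^3)
  dc1 <- 0.3 * kendo_i[idx] * chan$base / V
  dc2 <- -c_pred
  dc3 <- -c_pred * bW_i[idx] * design$logw
  G <- cbind(as.numeric(rowsum(dgdc * dc1, idx, reorder = FALSE)),
             as.numeric(rowsum(dgdc * dc2, idx, reorder = FALSE)),
             as.numeric(rowsum(dgdc * dc3, idx, reorder = FALSE)))
  om <- model$omega
  for (k in 1:3) {
    if (om[k] > 0) G[, k] <- G[, k] + eta[, k] / om[k]^2 else G[, k] <- 0
  }
  G
}

# Batched symmetric solves for the per-subject Newton systems (d <= 3),
# fully vectorized across subjects.  H is an n x (d*d) matrix (columns in
# column-major order); returns list(step = -H^{-1} G, det, pd).
.batch_spd <- function(H, G, d) {
  if (d == 1) {
    det <- H[, 1]
    return(list(step = -G / det, det = det,
                pd = is.finite(det) & det > 0))
  }
  if (d == 2) {
    a <- H[, 1]; b <- H[, 2]; c2 <- H[, 4]
    det <- a * c2 - b^2
    pd <- is.finite(det) & a > 0 & det > 0
    s1 <- -(c2 * G[, 1] - b * G[, 2]) / det
    s2 <- -(-b * G[, 1] + a * G[, 2]) / det
    return(list(step = cbind(s1, s2), det = det, pd = pd))
  }
  a <- H[, 1]; b <- H[, 2]; c3 <- H[, 3]
  e <- H[, 5]; f <- H[, 6]; i3 <- H[, 9]
  A11 <- e * i3 - f^2
  A12 <- c3 * f - b * i3
  A13 <- b * f - c3 * e
  det <- a * A11 + b * A12 + c3 * A13
  det2 <- a * e - b^2
  pd <- is.finite(det) & a > 0 & det2 > 0 & det > 0
  A22 <- a * i3 - c3^2
  A23 <- b * c3 - a * f
  A33 <- a * e - b^2
  s1 <- -(A11 * G[, 1] + A12 * G[, 2] + A13 * G[, 3]) / det
  s2 <- -(A12 * G[, 1] + A22 * G[, 2] + A23 * G[, 3]) / det
  s3 <- -(A13 * G[, 1] + A23 * G[, 2] + A33 * G[, 3]) / det
  list(step = cbind(s1, s2, s3), det = det, pd = pd)
}

.add_ridge <- function(H, ridge, d) {
  H2 <- H
  for (j in seq_len(d)) H2[, (j - 1) * d + j] <- H2[, (j - 1) * d + j] + ridge
  H2
}

# Analytic Hessians of the inner objective, batched across subjects:
# returns n x (d*d) matrix (column-major per subject) or NULL on failure
.inner_hess <- function(eta, design, model, chan, active) {
  idx <- design$idx
  b <- model$sigma_prop
  kendo_i <- model$kendo * exp(eta[, 1])
  fV_i <- model$fV * exp(eta[, 2])
  bW_i <- model$betaW * exp(eta[, 3])
  u <- kendo_i[idx] * chan$base
  P <- u + chan$extra + design$S
  V <- fV_i[idx] * exp(bW_i[idx] * design$logw)
  c_pred <- 0.3 * P / V
  if (any(!is.finite(c_pred) | c_pred <= 0)) return(NULL)
  r <- design$y - c_pred
  phi1 <- 1 / c_pred - r / (b^2 * c_pred^2) - r^2 / (b^2 * c_pred^3)
  phi2 <- -1 / c_pred^2 + 1 / (b^2 * c_pred^2) + 4 * r / (b^2 * c_pred^3) +
    3 * r^2 / (b^2 * c_pred^4)
  A <- 0.3 * u / V                      # dc/deta1
  bWL <- bW_i[idx] * design$logw
  dc3 <- -c_pred * bWL                  # dc/deta3  (dc/deta2 = -c)
  t11 <- phi2 * A^2 + phi1 * A
  t12 <- -phi2 * A * c_pred - phi1 * A
  t13 <- phi2 * A * dc3 - phi1 * A * bWL
  t22 <- phi2 * c_pred^2 + phi1 * c_pred
  t23 <- phi2 * c_pred^2 * bWL + phi1 * c_pred * bWL
  t33 <- phi2 * dc3^2 + phi1 * (c_pred * bWL^2 - c_pred * bWL)
  M <- cbind(as.numeric(rowsum(t11, idx, reorder = FALSE)),
             as.numeric(rowsum(t12, idx, reorder = FALSE)),
             as.numeric(rowsum(t13, idx, reorder = FALSE)),
             as.numeric(rowsum(t22, idx, reorder = FALSE)),
             as.numeric(rowsum(t23, idx, reorder = FALSE)),
             as.numeric(rowsum(t33, idx, reorder = FALSE)))
  om <- model$omega
  for (k in 1:3) if (om[k] > 0) {
    j <- c(1, 4, 6)[k]
    M[, j] <- M[, j] + 1 / om[k]^2
  }
  d <- length(active)
  H <- matrix(0, nrow(eta), d * d)
  pos <- matrix(c(1, 2, 3, 2, 4, 5, 3, 5, 6), 3, 3)
  for (j in seq_len(d)) for (k in seq_len(d))
    H[, (j - 1) * d + k] <- M[, pos[active[k], active[j]]]
  H
}

# Vectorized per-subject Newton search for the conditional modes.
# Returns list(eta, g, H (n x d*d), logdet, active, ok)
.inner_modes <- function(design, model, chan, eta_start = NULL,
                         tol = 1e-7, max_iter = 60) {
  n <- design$n
  active <- which(model$omega > 0)
  d <- length(active)
  eta <- if (is.null(eta_start)) matrix(0, n, 3) else eta_start
  eta[, setdiff(1:3, active)] <- 0
  if (d == 0) {
    res <- .inner_obj(eta, design, model, chan)
    return(list(eta = eta, g = res$g, H = NULL, logdet = numeric(n),
                active = active, ok = all(is.finite(res$g))))
  }
  g <- .inner_obj(eta, design, model, chan)$g
  if (any(!is.finite(g))) {
    # fall back to the origin for subjects whose warm start is infeasible
    eta[!is.finite(g), ] <- 0
    g <- .inner_obj(eta, design, model, chan)$g
    if (any(!is.finite(g))) return(list(ok = FALSE))
  }
  for (iter in seq_len(max_iter)) {
    G <- .inner_grad(eta, design, model, chan)
    if (is.null(G)) return(list(ok = FALSE))
    Ga <- G[, active, drop = FALSE]
    if (max(abs(Ga)) < tol && iter > 1) break
    H <- .inner_hess(eta, design, model, chan, active)
    if (is.null(H)) return(list(ok = FALSE))
    ridge <- rep(0, n)
    for (rep_i in 1:30) {
      sol <- .batch_spd(.add_ridge(H, ridge, d), Ga, d)
      if (all(sol$pd)) break
      ridge[!sol$pd] <- pmax(ridge[!sol$pd] * 10, 1e-4)
      if (any(ridge > 1e8)) return(list(ok = FALSE))
    }
    step <- matrix(0, n, 3)
    step[, active] <- sol$step
    # per-subject backtracking line search
    alpha <- rep(1, n)
    improved <- rep(FALSE, n)
    eta_new <- eta
    for (ls in 1:12) {
      trial <- eta + step * alpha
      trial[improved, ] <- eta_new[improved, ]
      g_try <- .inner_obj(trial, design, model, chan)$g
      better <- is.finite(g_try) & (g_try <= g) & !improved
      if (any(better)) {
        eta_new[better, ] <- trial[better, ]
        g[better] <- g_try[better]
        improved <- improved | better
      }
      if (all(improved)) break
      alpha[!improved] <- alpha[!improved] / 2
    }
    if (!any(improved)) break
    eta <- eta_new
  }
  # A warm start can strand a subject in a poor local basin of the (possibly
  # multimodal) conditional-density surface, which would make the outer
  # objective history-dependent.  The origin (the prior mean) is therefore
  # always solved as well, and the better mode kept per subject, so the
  # origin solution provides a path-independent floor.
  if (!is.null(eta_start)) {
    res <- .inner_modes(design, model, chan, eta_start = NULL,
                        tol = tol, max_iter = max_iter)
    if (isTRUE(res$ok)) {
      replace_i <- res$g < g
      if (any(replace_i)) {
        eta[replace_i, ] <- res$eta[replace_i, , drop = FALSE]
        g[replace_i] <- res$g[replace_i]
      }
    }
  }
  # final Hessian at the mode (for the Laplace determinant)
  G <- .inner_grad(eta, design, model, chan)
  if (is.null(G)) return(list(ok = FALSE))
  Ga <- G[, active, drop = FALSE]
  H <- .inner_hess(eta, design, model, chan, active)
  if (is.null(H)) return(list(ok = FALSE))
  det <- .batch_spd(H, Ga, d)$det
  g <- .inner_obj(eta, design, model, chan)$g
  list(eta = eta, g = g, H = H, logdet = log(pmax(det, 1e-300)),
       active = active, ok = all(is.finite(g)) && all(det > 0))
}

# -2 log marginal likelihood given conditional modes
.m2ll_from_modes <- function(modes, model, method = "laplace", nodes = 5,
                             design = NULL, chan = NULL) {
  active <- which(model$omega > 0)
  d <- length(active)
  n <- length(modes$g)
  if (d == 0) return(2 * sum(modes$g))
  logdet <- modes$logdet
  if (method == "laplace" || nodes == 1)
    return(sum(2 * modes$g - d * log(2 * pi) + logdet))
  # adaptive Gauss-Hermite centred at the mode, scaled by the mode Hessian;
  # all nodes of a subject are evaluated in one stacked pass
  gh <- .gauss_hermite(nodes)
  zg <- as.matrix(expand.grid(rep(list(seq_len(nodes)), d)))
  Z <- matrix(gh$x[zg], ncol = d)
  logW <- rowSums(matrix(log(gh$w[zg]), ncol = d))
  K <- nrow(Z)
  m2 <- 0
  for (i in seq_len(n)) {
    Hi <- matrix(modes$H[i, ], d, d)
    # a non-PD mode Hessian only degrades the node placement, not the
    # validity of the quadrature; regularize until factorizable
    ridge <- 0
    repeat {
      R <- tryCatch(chol(Hi + diag(ridge, d)), error = function(e) NULL)
      if (!is.null(R)) break
      ridge <- max(2 * ridge, 1e-6 * max(1, abs(diag(Hi))))
    }
    # eta = mode + sqrt(2) * R^{-1} z
    E <- matrix(rep(modes$eta[i, ], K), ncol = 3, byrow = TRUE)
    E[, active] <- E[, active, drop = FALSE] +
      sqrt(2) * t(backsolve(R, t(Z)))
    rows <- which(design$idx == i)
    nobs <- length(rows)
    big <- list(idx = rep(seq_len(K), each = nobs),
                y = rep(design$y[rows], K), S = rep(design$S[rows], K),
                logw = rep(design$logw[rows], K))
    ch_big <- list(base = rep(chan$base[rows], K),
                   extra = rep(chan$extra[rows], K))
    gvals <- .inner_obj(E, big, model, ch_big)$g
    logLi <- .logsumexp(logW - gvals + rowSums(Z^2)) +
      d / 2 * log(2) - sum(log(diag(R)))
    m2 <- m2 - 2 * logLi
  }
  m2
}

# encode/decode the outer parameter vector (log scale for positive params,
# identity for feedback coefficients)
.theta_names <- function(estimate, model) {
  nm <- intersect(c("kendo", "fV", "betaW", "omega_kendo", "omega_fV",
                    "omega_betaW", "sigma_prop"), estimate)
  if (!is.null(model$feedback) && "feedback" %in% estimate) {
    fb <- model$feedback
    k <- if (fb$coupling == "multiplicative") {
      if (fb$f %in% c("power_ratio", "log_power_ratio")) "fb_beta" else
        character(0)
    } else {
      paste0("fb_beta", seq_along(fb$betas))
    }
    nm <- c(nm, k)
  }
  nm
}

.encode_theta <- function(model, nm, scales = NULL) {
  th <- numeric(length(nm)); names(th) <- nm
  for (p in nm) {
    th[p] <- switch(p,
      kendo = log(model$kendo), fV = log(model$fV), betaW = log(model$betaW),
      omega_kendo = log(max(model$omega["kendo"], 1e-3)),
      omega_fV = log(max(model$omega["fV"], 1e-3)),
      omega_betaW = log(max(model$omega["betaW"], 1e-3)),
      sigma_prop = log(model$sigma_prop),
      fb_beta = model$feedback$beta,
      {
        j <- as.integer(sub("fb_beta", "", p))
        model$feedback$betas[j]
      })
    if (!is.null(scales) && p %in% names(scales)) th[p] <- th[p] / scales[[p]]
  }
  th
}

.decode_theta <- function(theta, model, nm, scales = NULL) {
  for (p in nm) {
    v <- theta[[p]]
    if (!is.null(scales) && p %in% names(scales)) v <- v * scales[[p]]
    if (p %in% c("kendo", "fV", "betaW", "sigma_prop")) model[[p]] <- exp(v)
    else if (p == "omega_kendo") model$omega["kendo"] <- exp(v)
    else if (p == "omega_fV") model$omega["fV"] <- exp(v)
    else if (p == "omega_betaW") model$omega["betaW"] <- exp(v)
    else if (p == "fb_beta") model$feedback$beta <- v
    else {
      j <- as.integer(sub("fb_beta", "", p))
      model$feedback$betas[j] <- v
    }
  }
  model
}

# characteristic magnitude of each free feedback coefficient: the value at
# which its contribution to the production integral rivals the endogenous
# baseline.  Keeps the outer optimization well-scaled, since e.g. an
# additive coefficient on raw TSH (hundreds of mU/l at diagnosis) lives at
# a scale orders of magnitude below the log-parameters.
.fb_scales <- function(design, model, nm) {
  fb_nm <- nm[grepl("^fb_beta", nm)]
  if (!length(fb_nm)) return(NULL)
  scales <- stats::setNames(rep(1, length(fb_nm)), fb_nm)
  fb <- model$feedback
  base_mag <- model$kendo / model$kel
  for (p in fb_nm) {
    if (p == "fb_beta") next  # power exponent, already O(1)
    j <- as.integer(sub("fb_beta", "", p))
    probe <- model
    if (fb$coupling == "categorical") {
      probe$feedback$betas <- replace(numeric(length(fb$betas)), j, 1)
    } else {
      probe$feedback$betas <- 1
    }
    ch <- .endo_channels(design, probe)
    mag <- stats::quantile(abs(ch$extra), 0.95, names = FALSE)
    if (is.finite(mag) && mag > 0) scales[p] <- base_mag / mag
  }
  scales
}

# ---- exported likelihood / fitting interface --------------------------------

#' -2 log marginal likelihood of a population model
#'
#' Computes the marginal (random effects integrated out) -2 log-likelihood of
#' the observed FT4 data under the proportional-error observation model.  The
#' integral over each subject's log-normal random effects is approximated by
#' a Laplace approximation at the conditional mode (`method = "laplace"`) or
#' by adaptive Gauss-Hermite quadrature centred and scaled at the mode
#' (`method = "agq"`, `nodes^d` points per subject).  With all IIV standard
#' deviations zero the marginal likelihood is the plain product of
#' proportional-error Gaussians and is summed in closed form.
#'
#' @param model an [ft4_model()].
#' @param data an `ft4_dataset`.
#' @param method `"agq"` (default, adaptive Gauss-Hermite) or `"laplace"`.
#' @param nodes quadrature nodes per dimension for `"agq"`.
#' @param response which observation column to treat as the response.
#' @return scalar -2 log-likelihood (deterministic).
#' @export
minus2ll <- function(model, data, method = c("agq", "laplace"), nodes = 5,
                     response = c("auto", "ft4_norm", "ft4")) {
  method <- match.arg(method)
  design <- .build_design(data, model, response)
  model$wref <- design$wref
  chan <- .endo_channels(design, model)
  modes <- .inner_modes(design, model, chan)
  if (!isTRUE(modes$ok)) stop("non-positive predictions: likelihood undefined")
  .m2ll_from_modes(modes, model, method = method, nodes = nodes,
                   design = design, chan = chan)
}

#' Fit the FT4 population model by maximum marginal likelihood
#'
#' Nonlinear mixed-effects estimation of the structural FT4 model: typical
#' values of `kendo`, `fV`, `betaW`, their log-normal IIV standard
#' deviations, the proportional residual error and (optionally) TSH-feedback
#' coefficients are estimated by maximizing the Laplace-approximate marginal
#' likelihood.  The inner problem (per-subject conditional modes) is solved
#' by a damped Newton iteration with analytic gradients; the outer problem by
#' quasi-Newton (`nlminb`) on log-transformed parameters.  `ka`, `kel` and
#' `F` stay fixed (pass them in `start`).  The procedure is deterministic:
#' identical data and settings reproduce the fit bit-identically.
#'
#' @param data an `ft4_dataset` (normalized FT4 used automatically when
#'   present).
#' @param start an [ft4_model()] providing starting values, fixed constants
#'   and the feedback specification.
#' @param estimate character vector naming the free parameters, from
#'   `"kendo"`, `"fV"`, `"betaW"`, `"omega_kendo"`, `"omega_fV"`,
#'   `"omega_betaW"`, `"sigma_prop"`, `"feedback"`.
#' @param response observation column: `"auto"`, `"ft4_norm"` or `"ft4"`.
#' @param se compute standard errors from the observed Fisher information
#'   (finite differences of the objective); disable for speed in
#'   simulation loops.
#' @param evaluate_only skip the optimization and evaluate `start` as-is
#'   (conditional modes, likelihood, diagnostics); useful for model
#'   evaluation and simulation studies at known parameters.
#' @param control list: `rel.tol`, `iter.max`, `eval.max` passed to
#'   [stats::nlminb()]; `lik_method`, `lik_nodes` select how the reported
#'   -2LL is computed (default adaptive Gauss-Hermite with 5 nodes per
#'   dimension; the optimization itself always uses the Laplace objective).
#' @return object of class `ft4_fit`: fitted model, coefficient table,
#'   `minus2ll`, per-subject empirical Bayes estimates, shrinkage,
#'   convergence flag.
#' @seealso [minus2ll()], [compare_models()], [empirical_bayes()], [vpc()]
#' @export
fit_ft4 <- function(data, start = ft4_model(),
                    estimate = c("kendo", "fV", "betaW", "omega_kendo",
                                 "omega_fV", "omega_betaW", "sigma_prop"),
                    response = c("auto", "ft4_norm", "ft4"),
                    se = TRUE, evaluate_only = FALSE, control = list()) {
  stopifnot(inherits(start, "ft4_model"))
  ctrl <- utils::modifyList(list(rel.tol = 1e-8, iter.max = 300,
                                 eval.max = 800, lik_method = "agq",
                                 lik_nodes = 5), control)
  design <- .build_design(data, start, response)
  start$wref <- design$wref
  nm <- .theta_names(estimate, start)
  if (!length(nm)) stop("nothing to estimate")
  scales <- .fb_scales(design, start, nm)
  theta0 <- .encode_theta(start, nm, scales)
  env <- new.env(parent = emptyenv())
  env$eta <- matrix(0, design$n, 3)
  fb_coef_free <- grepl("^fb_beta", nm)
  env$chan0 <- if (!any(fb_coef_free)) .endo_channels(design, start) else NULL
  obj <- function(theta) {
    names(theta) <- nm
    m <- .decode_theta(theta, start, nm, scales)
    chan <- if (any(fb_coef_free)) .endo_channels(design, m) else env$chan0
    modes <- .inner_modes(design, m, chan, eta_start = env$eta)
    if (!isTRUE(modes$ok)) return(1e10)
    val <- .m2ll_from_modes(modes, m, method = "laplace")
    if (!is.finite(val)) return(1e10)
    env$eta <- modes$eta
    val
  }
  lower <- ifelse(grepl("^omega", nm), log(1e-3), -Inf)
  upper <- rep(Inf, length(nm))
  opt <- if (evaluate_only) {
    list(par = theta0, convergence = 0L, message = "evaluation only")
  } else {
    stats::nlminb(theta0, obj, lower = lower, upper = upper,
                  control = list(rel.tol = ctrl$rel.tol,
                                 iter.max = ctrl$iter.max,
                                 eval.max = ctrl$eval.max))
  }
  theta_hat <- opt$par; names(theta_hat) <- nm
  fitted_model <- .decode_theta(theta_hat, start, nm, scales)
  chan <- .endo_channels(design, fitted_model)
  modes <- .inner_modes(design, fitted_model, chan, eta_start = env$eta)
  if (!isTRUE(modes$ok))
    stop("likelihood undefined at the returned estimates; fit failed")
  m2 <- .m2ll_from_modes(modes, fitted_model, method = ctrl$lik_method,
                         nodes = ctrl$lik_nodes, design = design, chan = chan)
  # coefficient table on the natural scale
  nat <- vapply(nm, function(p) switch(p,
    kendo = fitted_model$kendo, fV = fitted_model$fV,
    betaW = fitted_model$betaW,
    omega_kendo = unname(fitted_model$omega["kendo"]),
    omega_fV = unname(fitted_model$omega["fV"]),
    omega_betaW = unname(fitted_model$omega["betaW"]),
    sigma_prop = fitted_model$sigma_prop,
    fb_beta = fitted_model$feedback$beta,
    fitted_model$feedback$betas[as.integer(sub("fb_beta", "", p))]),
    numeric(1))
  se_nat <- rse <- rep(NA_real_, length(nm))
  if (se && !evaluate_only) {
    Hm <- .fd_hessian(obj, theta_hat)
    Vth <- tryCatch(2 * solve(Hm), error = function(e) NULL)
    if (!is.null(Vth) && all(diag(Vth) > 0)) {
      sd_th <- stats::setNames(sqrt(diag(Vth)), nm)
      # undo the internal rescaling of feedback coefficients
      if (!is.null(scales))
        sd_th[names(scales)] <- sd_th[names(scales)] * scales
      log_scale <- !grepl("^fb_beta", nm)
      # delta method: parameters estimated on the log scale
      se_nat <- ifelse(log_scale, nat * sd_th, sd_th)
      rse <- ifelse(log_scale, 100 * sd_th, 100 * sd_th / abs(nat))
    }
  }
  active <- which(fitted_model$omega > 0)
  eta_sd <- apply(modes$eta, 2, stats::sd)
  shrink <- rep(NA_real_, 3)
  for (k in active)
    shrink[k] <- (1 - eta_sd[k] / fitted_model$omega[k]) * 100
  names(shrink) <- c("kendo", "fV", "betaW")
  coefs <- data.frame(parameter = nm, estimate = unname(nat),
                      se = se_nat, rse_pct = rse, stringsAsFactors = FALSE)
  structure(list(model = fitted_model, coefficients = coefs,
                 minus2ll = m2, eta = modes$eta,
                 eta_hessians = modes$H, shrinkage_pct = shrink,
                 converged = opt$convergence == 0,
                 message = opt$message, n_subjects = design$n,
                 n_obs = sum(design$n_obs), response = design$response,
                 wref = design$wref, estimate = nm, design = design,
                 data = data, lik_method = ctrl$lik_method,
                 call = match.call()),
            class = "ft4_fit")
}

.fd_hessian <- function(f, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  hs <- pmax(abs(x), 1) * h
  f0 <- f(x)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + hs[i]; fp[i] <- f(xp)
    xm <- x; xm[i] <- x[i] - hs[i]; fm[i] <- f(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / hs[i]^2
  }
  for (i in seq_len(p)) for (j in seq_len(p)) if (i < j) {
    xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + hs[c(i, j)]
    xpm <- x; xpm[i] <- x[i] + hs[i]; xpm[j] <- x[j] - hs[j]
    xmp <- x; xmp[i] <- x[i] - hs[i]; xmp[j] <- x[j] + hs[j]
    xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - hs[c(i, j)]
    H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
      (4 * hs[i] * hs[j])
  }
  H
}

#' Per-subject empirical Bayes estimates and shrinkage
#'
#' Returns the conditional-mode random effects, the implied individual
#' parameters, and the shrinkage of each random effect,
#' `(1 - sd(eta_k) / omega_k) * 100` percent.  High shrinkage flags random
#' effects that the data cannot individualize.  Random effects with
#' `omega = 0` have undefined shrinkage (reported `NA`).
#'
#' @param fit an `ft4_fit`.
#' @return data.frame with one row per subject: `eta_*` columns, individual
#'   `kendo`, `fV`, `betaW`; attribute `"shrinkage_pct"`.
#' @export
empirical_bayes <- function(fit) {
  stopifnot(inherits(fit, "ft4_fit"))
  ids <- vapply(fit$design$subjects, `[[`, character(1), "id")
  m <- fit$model
  out <- data.frame(subject_id = ids,
                    eta_kendo = fit$eta[, 1], eta_fV = fit$eta[, 2],
                    eta_betaW = fit$eta[, 3],
                    kendo = m$kendo * exp(fit$eta[, 1]),
                    fV = m$fV * exp(fit$eta[, 2]),
                    betaW = m$betaW * exp(fit$eta[, 3]),
                    stringsAsFactors = FALSE)
  attr(out, "shrinkage_pct") <- fit$shrinkage_pct
  out
}

#' Likelihood-ratio comparison of nested fits
#'
#' `delta_ofv = minus2ll(reduced) - minus2ll(full)` compared against a
#' chi-square with `df` degrees of freedom.  A materially negative
#' `delta_ofv` (the full model fitting worse than its nested reduction)
#' is flagged as an approximation or convergence artifact.
#'
#' @param fit_reduced,fit_full `ft4_fit` objects for nested models.
#' @param df degrees of freedom; default the difference in number of
#'   estimated parameters.
#' @param alpha significance level (default 0.05).
#' @return list with `delta_ofv`, `df`, `p_value`, `significant`, `artifact`.
#' @export
compare_models <- function(fit_reduced, fit_full, df = NULL, alpha = 0.05) {
  stopifnot(inherits(fit_reduced, "ft4_fit"), inherits(fit_full, "ft4_fit"))
  if (is.null(df)) df <- length(fit_full$estimate) - length(fit_reduced$estimate)
  if (df < 1) stop("full model must have more free parameters than reduced")
  d <- fit_reduced$minus2ll - fit_full$minus2ll
  artifact <- d < -1e-3
  d_eff <- max(d, 0)
  p <- stats::pchisq(d_eff, df = df, lower.tail = FALSE)
  list(delta_ofv = d, df = df, p_value = p, significant = p < alpha,
       artifact = artifact)
}
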