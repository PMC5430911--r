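#' Serial (hierarchical) orthogonalization of regressor columns
#'
#' Residualizes each column against all earlier columns in order, so column
#' `k` keeps only variance not already carried by columns `1..k-1`. The
#' first column is returned unchanged. Shared variance between two
#' modulators is thereby attributed to whichever comes first in the stated
#' order (here: evidence, then prior, then their interaction).
#'
#' @param columns Numeric matrix (or list of equal-length vectors), columns
#'   in orthogonalization order.
#' @return Matrix of the same shape; later columns orthogonal to earlier
#'   ones. A zero-norm earlier column is skipped with a warning.
#' @export
#' @examples
#' m <- cbind(a = rnorm(50), b = rnorm(50))
#' out <- serial_orthogonalize(m)
#' abs(sum(out[, 1] * out[, 2])) < 1e-10
serial_orthogonalize <- function(columns) {
  X <- if (is.list(columns) && !is.data.frame(columns)) {
    do.call(cbind, columns)
  } else {
    as.matrix(columns)
  }
  if (ncol(X) < 1) abort("need at least one column")
  out <- X
  warned <- integer(0)
  for (k in seq_len(ncol(X))[-1]) {
    v <- out[, k]
    for (j in seq_len(k - 1)) {
      u <- out[, j]
      nu <- sum(u^2)
      if (nu < 1e-24) {
        if (!j %in% warned) {
          warn(sprintf("column %d has zero norm; skipped in orthogonalization", j))
          warned <- c(warned, j)
        }
        next
      }
      v <- v - u * (sum(u * v) / nu)
    }
    out[, k] <- v
  }
  out
}

#' Discrete-cosine high-pass basis
#'
#' DCT regressors spanning fluctuations slower than `cutoff_s`, the standard
#' way to implement a high-pass filter inside a GLM.
#'
#' @param n_volumes Number of scans.
#' @param tr Repetition time (s).
#' @param cutoff_s High-pass cutoff period (s), default 128.
#' @return Matrix `n_volumes x K` (possibly zero columns) with columns
#'   `hp_1..hp_K`.
#' @export
dct_highpass_basis <- function(n_volumes, tr, cutoff_s = 128) {
  K <- floor(2 * n_volumes * tr / cutoff_s)
  v <- seq_len(n_volumes) - 1
  if (K < 1) {
    return(matrix(numeric(0), nrow = n_volumes, ncol = 0))
  }
  B <- vapply(seq_len(K), function(k) {
    sqrt(2 / n_volumes) * cos(pi * (2 * v + 1) * k / (2 * n_volumes))
  }, numeric(n_volumes))
  colnames(B) <- paste0("hp_", seq_len(K))
  B
}

#' Second-degree polynomial expansion of motion parameters
#'
#' @param motion Matrix or data frame of motion estimates (volumes x 6).
#' @return Matrix with the original columns plus their squares.
#' @export
expand_motion <- function(motion) {
  m <- as.matrix(motion)
  nm <- colnames(m) %||% paste0("mot", seq_len(ncol(m)))
  out <- cbind(m, m^2)
  colnames(out) <- c(nm, paste0(nm, "_sq"))
  out
}

#' Build the parametric fMRI design matrix
#'
#' Constructs, per condition, the categorical regressors (preparation
#' boxcar, inference boxcar, control boxcar, motor stick) and the parametric
#' modulators (prior on preparation; evidence, prior and their interaction
#' on inference). Modulator values are mean-centered within condition,
#' multiplied into their parent boxcar on a microtime grid, convolved with
#' the canonical HRF, downsampled to the scan times, and finally the
#' inference modulators are serially orthogonalized in the fixed order
#' evidence, prior, interaction. With two conditions this yields 16 task
#' regressors (8 categorical + 8 parametric).
#'
#' @param events Event table as produced by [events_table()] /
#'   [read_events()], optionally with a `condition` column (e.g. `task_type`
#'   from [assemble_session()]); without one, a single condition `"task"` is
#'   assumed.
#' @param modulators Data frame keyed by `trial_index` (and `condition` when
#'   present) with columns `evidence`, `prior`, and optionally `interaction`
#'   (default: their product) for non-control trials.
#' @param tr Repetition time (s).
#' @param n_volumes Number of scans the matrix must cover.
#' @param hrf An [hrf_spec()] or [canonical_hrf()] kernel.
#' @param highpass Add 128 s DCT high-pass columns?
#' @param hp_cutoff_s High-pass cutoff period (s).
#' @param nuisance Optional matrix of nuisance covariates (volumes x q),
#'   e.g. [expand_motion()] output.
#' @return An object of class `design_matrix`: list with the numeric matrix
#'   `X` (named columns), `task_cols`, `ortho_record`, `tr`, `n_volumes`.
#' @export
build_design_matrix <- function(events, modulators, tr, n_volumes,
                                hrf = hrf_spec(), highpass = TRUE,
                                hp_cutoff_s = 128, nuisance = NULL) {
  hv <- hrf_values(hrf)
  dt <- hv$dt
  total_s <- n_volumes * tr
  if (!"condition" %in% names(events)) events$condition <- "task"
  if (!"condition" %in% names(modulators) && length(unique(events$condition)) == 1) {
    modulators$condition <- unique(events$condition)
  }
  late <- events$onset + events$duration > total_s + 1e-9
  if (any(late)) {
    abort(sprintf("events beyond scan end (%.1f s): trial indices %s",
                  total_s,
                  paste(unique(events$trial_index[late]), collapse = ", ")))
  }
  m <- ceiling(total_s / dt)
  grid_idx <- function(t) pmin(m, pmax(1L, floor(t / dt) + 1L))
  scan_idx <- grid_idx((seq_len(n_volumes) - 1) * tr)

  boxcar <- function(onsets, durations, amplitude = 1) {
    x <- numeric(m)
    amplitude <- rep_len(amplitude, length(onsets))
    for (i in seq_along(onsets)) {
      i0 <- grid_idx(onsets[i])
      i1 <- grid_idx(onsets[i] + max(durations[i], dt) - 1e-9)
      x[i0:i1] <- x[i0:i1] + amplitude[i]
    }
    x
  }
  make_col <- function(onsets, durations, amplitude = 1) {
    convolve_hrf(boxcar(onsets, durations, amplitude), hv$values)[scan_idx]
  }

  conditions <- unique(events$condition[events$phase != "control" |
                                          is.na(events$phase)])
  conditions <- conditions[!is.na(conditions)]
  cols <- list()
  ortho_record <- list()

  for (cond in conditions) {
    ev_c <- events[events$condition == cond, ]
    task_ev <- ev_c[ev_c$phase %in% c("induction", "testing"), ]
    ctrl_ev <- ev_c[ev_c$phase == "control", ]

    prep <- task_ev[task_ev$trial_type == "preparation", ]
    act <- task_ev[task_ev$trial_type == "action", ]
    resp <- task_ev[task_ev$trial_type == "response", ]

    mod_c <- modulators[modulators$condition == cond, , drop = FALSE]
    mi <- match(act$trial_index, mod_c$trial_index)
    if (any(is.na(mi))) {
      abort(sprintf("missing modulator values for trials: %s",
                    paste(act$trial_index[is.na(mi)], collapse = ", ")))
    }
    evid <- mod_c$evidence[mi]
    prior <- mod_c$prior[mi]
    inter <- if ("interaction" %in% names(mod_c)) {
      mod_c$interaction[mi]
    } else {
      evid * prior
    }
    if (any(is.na(evid)) || any(is.na(prior)) || any(is.na(inter))) {
      abort("modulators must be non-missing for every inference event")
    }
    mi_p <- match(prep$trial_index, mod_c$trial_index)
    prior_prep <- mod_c$prior[mi_p]

    cols[[paste0("prep_", cond)]] <- make_col(prep$onset, prep$duration)
    cols[[paste0("prep_", cond, "_x_prior")]] <-
      make_col(prep$onset, prep$duration, prior_prep - mean(prior_prep))
    cols[[paste0("infer_", cond)]] <- make_col(act$onset, act$duration)
    par_cols <- cbind(
      evidence = make_col(act$onset, act$duration, evid - mean(evid)),
      prior = make_col(act$onset, act$duration, prior - mean(prior)),
      interaction = make_col(act$onset, act$duration, inter - mean(inter))
    )
    par_cols <- serial_orthogonalize(par_cols)
    for (nm in colnames(par_cols)) {
      cols[[paste0("infer_", cond, "_x_", nm)]] <- par_cols[, nm]
    }
    ortho_record[[cond]] <- list(
      parent = paste0("infer_", cond),
      order = c("evidence", "prior", "interaction")
    )
    if (nrow(ctrl_ev) > 0) {
      c_on <- tapply(ctrl_ev$onset, ctrl_ev$trial_index, min)
      c_off <- tapply(ctrl_ev$onset + ctrl_ev$duration, ctrl_ev$trial_index, max)
      cols[[paste0("control_", cond)]] <- make_col(c_on, c_off - c_on)
    } else {
      cols[[paste0("control_", cond)]] <- numeric(n_volumes)
    }
    cols[[paste0("motor_", cond)]] <- make_col(resp$onset, rep(dt, nrow(resp)))
  }

  X <- do.call(cbind, cols)
  task_cols <- colnames(X)
  if (highpass) {
    X <- cbind(X, dct_highpass_basis(n_volumes, tr, hp_cutoff_s))
  }
  if (!is.null(nuisance)) {
    nz <- as.matrix(nuisance)
    colnames(nz) <- colnames(nz) %||% paste0("nuis_", seq_len(ncol(nz)))
    X <- cbind(X, nz)
  }
  X <- cbind(X, intercept = 1)

  structure(
    list(X = X, task_cols = task_cols, ortho_record = ortho_record,
         tr = tr, n_volumes = n_volumes, dt = dt,
         highpass = highpass, hp_cutoff_s = hp_cutoff_s),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d regressors (%d task)\n",
              nrow(x$X), ncol(x$X), length(x$task_cols)))
  cat("  task columns:", paste(x$task_cols, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as_tibble.design_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$X))
  dplyr::mutate(out, volume = dplyr::row_number(), .before = 1)
}
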