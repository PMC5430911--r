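#' Bilinear DCM model specification
#'
#' A bilinear dynamic causal model over the three regions of the
#' intention-inference network — a preparatory region (SMA or dACC), the
#' mPFC, and the TPJ — with neural dynamics
#' \deqn{\dot z = \Big(A + \sum_j u_j B_j\Big) z + C u.}
#' `A` holds the intrinsic connections (negative self-decay on the
#' diagonal), each `B[[j]]` the modulation of those connections by input
#' `j`, and `C` the driving-input weights.
#'
#' @param A Square numeric matrix (regions x regions), row = target,
#'   column = source; diagonal entries must be negative.
#' @param B Named list of square matrices, one per modulatory input; entries
#'   must be zero wherever `A` is zero (a modulator can only scale an
#'   existing connection).
#' @param C Numeric matrix regions x inputs (driving weights). Its columns
#'   define the input order; modulator names in `B` must appear among the
#'   input names.
#' @param id Model identifier.
#' @param family Family identifier (1-5 in the default space).
#' @param regions Region names.
#' @return Object of class `dcm_model`.
#' @export
dcm_model <- function(A, B = list(), C, id = "m1", family = NA_integer_,
                      regions = rownames(A) %||% paste0("r", seq_len(nrow(A)))) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) abort("`A` must be square")
  if (any(diag(A) >= 0)) abort("self-connections (diag of A) must be negative")
  C <- as.matrix(C)
  if (nrow(C) != nrow(A)) abort("`C` must have one row per region")
  inputs <- colnames(C) %||% paste0("u", seq_len(ncol(C)))
  colnames(C) <- inputs
  for (nm in names(B)) {
    Bj <- as.matrix(B[[nm]])
    if (!all(dim(Bj) == dim(A))) abort("each B matrix must match A in shape")
    if (any(Bj[A == 0] != 0)) {
      abort(sprintf("B[[%s]] modulates a connection absent from A", nm))
    }
    if (!nm %in% inputs) {
      abort(sprintf("modulator `%s` has no matching input column in C", nm))
    }
  }
  dimnames(A) <- list(regions, regions)
  rownames(C) <- regions
  structure(list(id = id, family = family, A = A, B = B, C = C,
                 regions = regions, inputs = inputs),
            class = "dcm_model")
}

#' @export
print.dcm_model <- function(x, ...) {
  mods <- names(x$B)[vapply(x$B, function(m) any(m != 0), logical(1))]
  cat(sprintf("<dcm_model> %s (family %s), regions: %s\n",
              x$id, x$family, paste(x$regions, collapse = ", ")))
  cat(sprintf("  modulators: %s\n",
              if (length(mods)) paste(mods, collapse = ", ") else "none"))
  invisible(x)
}

# default connection progression: from fully connected down to
# the single forward prep -> mPFC connection
default_family_connections <- function() {
  list(
    `1` = c("prep->mPFC", "mPFC->prep", "mPFC->TPJ", "TPJ->mPFC",
            "prep->TPJ", "TPJ->prep"),
    `2` = c("prep->mPFC", "mPFC->prep", "mPFC->TPJ", "TPJ->mPFC"),
    `3` = c("prep->mPFC", "mPFC->prep", "mPFC->TPJ"),
    `4` = c("prep->mPFC", "mPFC->TPJ", "TPJ->mPFC"),
    `5` = c("prep->mPFC")
  )
}

#' Enumerate the anatomical model families
#'
#' Five families ordered by progressive removal of connections, from a
#' fully connected three-region network down to a minimal network with only
#' the forward preparation-to-mPFC connection. The default progression is a
#' configurable table; any family list mapping ids to `"from->to"`
#' connection sets may be substituted.
#'
#' @param connections Named list of character vectors of `"from->to"`
#'   connections, one element per family (default
#'   `default_family_connections()`).
#' @return Tibble with columns `family` (integer), `connections`
#'   (list-column), `n_connections`.
#' @export
enumerate_families <- function(connections = default_family_connections()) {
  regions <- c("prep", "mPFC", "TPJ")
  for (cs in connections) {
    parts <- strsplit(cs, "->", fixed = TRUE)
    ok <- vapply(parts, function(p) length(p) == 2 && all(p %in% regions),
                 logical(1))
    if (!all(ok)) abort("connections must be 'from->to' over prep, mPFC, TPJ")
  }
  tibble(
    family = as.integer(names(connections)),
    connections = unname(connections),
    n_connections = lengths(connections)
  )
}

connection_matrix <- function(conns, regions = c("prep", "mPFC", "TPJ")) {
  M <- matrix(0, length(regions), length(regions),
              dimnames = list(regions, regions))
  for (cs in conns) {
    p <- strsplit(cs, "->", fixed = TRUE)[[1]]
    M[p[2], p[1]] <- 1 # row = target, column = source
  }
  M
}

#' Enumerate the bilinear model space
#'
#' Builds 8 models per family (40 in the default five-family space). In
#' every model the intention type (INT) modulates the forward
#' preparation-to-mPFC connection; the 8 variants cross the modulated
#' mPFC--TPJ connection (forward TPJ-to-mPFC vs backward mPFC-to-TPJ) with
#' the modulator set on that connection (INT; PE; INT+PE; INT+PE+PExINT).
#' Modulation masks are intersected with the family's intrinsic
#' connections, so a family lacking the targeted connection simply carries
#' no such modulation. Driving inputs are fixed across families: the
#' preparation input enters the preparatory region and the inference input
#' enters the TPJ.
#'
#' @param families Tibble from [enumerate_families()].
#' @param self Negative self-decay placed on the diagonal of every `A`.
#' @param a_strength Value given to present intrinsic connections.
#' @param b_strength Value given to present modulatory entries.
#' @param c_strength Driving-input weight.
#' @return List of `dcm_model` objects with deterministic ids
#'   `f<family>_m<1-8>`.
#' @export
enumerate_models <- function(families = enumerate_families(), self = -1,
                             a_strength = 0.4, b_strength = 0.4,
                             c_strength = 1) {
  regions <- c("prep", "mPFC", "TPJ")
  inputs <- c("prep_input", "infer_input", "INT", "PE", "PExINT")
  directions <- c(forward = "TPJ->mPFC", backward = "mPFC->TPJ")
  mod_sets <- list("INT", "PE", c("INT", "PE"), c("INT", "PE", "PExINT"))

  models <- list()
  for (fi in seq_len(nrow(families))) {
    fam <- families$family[fi]
    Amask <- connection_matrix(families$connections[[fi]], regions)
    A <- Amask * a_strength
    diag(A) <- self
    C <- matrix(0, 3, 5, dimnames = list(regions, inputs))
    C["prep", "prep_input"] <- c_strength
    C["TPJ", "infer_input"] <- c_strength
    k <- 0
    for (dir in names(directions)) {
      target <- connection_matrix(directions[[dir]], regions)
      for (ms in mod_sets) {
        k <- k + 1
        B <- lapply(c(INT = "INT", PE = "PE", PExINT = "PExINT"), function(mod) {
          M <- matrix(0, 3, 3, dimnames = list(regions, regions))
          if (mod == "INT") {
            M <- M + connection_matrix("prep->mPFC", regions) * b_strength
          }
          if (mod %in% ms) M <- M + target * b_strength
          M * (Amask > 0) # only modulate connections the family contains
        })
        models[[length(models) + 1]] <- dcm_model(
          A = A, B = B, C = C,
          id = sprintf("f%d_m%d", fam, k), family = fam, regions = regions
        )
      }
    }
  }
  models
}

#' Integrate bilinear DCM neural dynamics
#'
#' Fixed-step fourth-order Runge-Kutta integration of
#' `dz/dt = (A + sum_j u_j B_j) z + C u`, inputs held constant within each
#' step.
#'
#' @param model A `dcm_model`.
#' @param inputs Matrix (microtime steps x inputs). Columns are matched to
#'   the model's input names when named, otherwise taken in order.
#' @param dt Integration step (s), > 0.
#' @param z0 Initial state (default zeros).
#' @return Matrix (steps x regions) of neural states (named columns).
#' @export
simulate_dcm <- function(model, inputs, dt = 0.1, z0 = NULL) {
  if (!inherits(model, "dcm_model")) abort("`model` must be a dcm_model")
  if (dt <= 0) abort("`dt` must be positive")
  ev <- eigen(model$A, only.values = TRUE)$values
  if (any(Re(ev) > 0)) {
    abort(sprintf("model %s has an unstable A matrix (positive real eigenvalue)",
                  model$id))
  }
  u <- as.matrix(inputs)
  if (!is.null(colnames(u))) {
    missing <- setdiff(model$inputs, colnames(u))
    if (length(missing)) {
      abort(sprintf("inputs missing column(s): %s", paste(missing, collapse = ", ")))
    }
    u <- u[, model$inputs, drop = FALSE]
  } else if (ncol(u) != length(model$inputs)) {
    abort("unnamed `inputs` must have one column per model input")
  }
  k <- length(model$regions)
  z <- z0 %||% numeric(k)
  Bmats <- model$B[model$inputs[model$inputs %in% names(model$B)]]
  bidx <- match(names(Bmats), model$inputs) - 1L
  out <- tryCatch(
    dcm_rk4_cpp(model$A, unname(Bmats), model$C, u, as.integer(bidx), dt, z),
    error = function(e) {
      abort(sprintf("integration diverged for model %s", model$id))
    }
  )
  colnames(out) <- model$regions
  out
}

#' Build microtime DCM input series from an event table
#'
#' Constructs the five standard inputs of the intention-inference model
#' space on the integration grid: the preparation and inference driving
#' boxcars, the intention-type modulator INT (+1/-1 by condition during
#' inference, 0 elsewhere), the prior modulator PE (mean-centered prior
#' during inference), and their product PExINT.
#'
#' @param events Event table (see [events_table()]) with a `condition`
#'   column taking at most two values; the second (sorted) condition codes
#'   INT = +1.
#' @param modulators Data frame with `condition`, `trial_index`, `prior`.
#' @param dt Microtime step (s).
#' @param total_s Total duration covered (s).
#' @return Matrix (ceiling(total_s / dt) x 5) with named columns
#'   `prep_input`, `infer_input`, `INT`, `PE`, `PExINT`.
#' @export
dcm_inputs <- function(events, modulators, dt = 0.1, total_s = NULL) {
  if (!"condition" %in% names(events)) events$condition <- "task"
  total_s <- total_s %||% max(events$onset + events$duration)
  m <- ceiling(total_s / dt)
  idx <- function(t) pmin(m, pmax(1L, floor(t / dt) + 1L))
  fill <- function(onsets, durations, amp) {
    x <- numeric(m)
    amp <- rep_len(amp, length(onsets))
    for (i in seq_along(onsets)) {
      x[idx(onsets[i]):idx(onsets[i] + max(durations[i], dt) - 1e-9)] <- amp[i]
    }
    x
  }
  conds <- sort(unique(events$condition))
  if (length(conds) > 2) abort("at most two conditions are supported")
  task <- events[events$phase %in% c("induction", "testing"), ]
  prep <- task[task$trial_type == "preparation", ]
  act <- task[task$trial_type == "action", ]
  int_code <- if (length(conds) == 2) ifelse(act$condition == conds[2], 1, -1) else rep(1, nrow(act))
  key <- paste(act$condition, act$trial_index)
  mkey <- paste(modulators$condition %||% conds[1], modulators$trial_index)
  pe <- modulators$prior[match(key, mkey)]
  if (any(is.na(pe))) abort("missing prior values for some inference events")
  pe <- pe - mean(pe)
  cbind(
    prep_input = fill(prep$onset, prep$duration, 1),
    infer_input = fill(act$onset, act$duration, 1),
    INT = fill(act$onset, act$duration, int_code),
    PE = fill(act$onset, act$duration, pe),
    PExINT = fill(act$onset, act$duration, pe * int_code)
  )
}
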