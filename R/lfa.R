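## Stage 1: longitudinal bivariate confirmatory factor analysis under strong
## factorial invariance on wave-1-standardized items, and Bartlett factor
## score extraction per person-wave.

panel_meta_cols <- c("id", "wave_year", "age_years", "observed")

#' Standardize items to reference-wave means and SDs
#'
#' Transforms every item column by `(x - m_ref) / s_ref`, where the
#' reference mean and SD are computed from available cases at the
#' reference wave.  The same transform is applied to all waves, so later
#' wave means reflect raw drift on the reference wave's scale.
#'
#' @param panel long item panel (columns `id`, `wave_year`, `age_years`,
#'   items, optional `observed`)
#' @param ref_wave reference wave year (present in `wave_year`)
#' @param items item columns (default: all non-metadata columns)
#' @return list with `panel` (standardized) and `record` (data frame of
#'   class `standardization_record` with reference means and SDs)
#' @export
standardize_items <- function(panel, ref_wave = 2010, items = NULL) {
  if (is.null(items)) items <- setdiff(names(panel), panel_meta_cols)
  if (!ref_wave %in% panel$wave_year)
    stop("reference wave ", ref_wave, " not present in panel")
  ref <- panel[panel$wave_year == ref_wave, , drop = FALSE]
  m <- vapply(items, function(it) mean(ref[[it]], na.rm = TRUE), numeric(1))
  s <- vapply(items, function(it) stats::sd(ref[[it]], na.rm = TRUE), numeric(1))
  zero <- items[!is.finite(s) | s <= 0]
  if (length(zero))
    stop("zero-variance item(s) at reference wave: ",
         paste(zero, collapse = ", "))
  for (it in items) panel[[it]] <- (panel[[it]] - m[it]) / s[it]
  record <- data.frame(item = items, ref_mean = unname(m), ref_sd = unname(s),
                       ref_wave = ref_wave, stringsAsFactors = FALSE)
  class(record) <- c("standardization_record", "data.frame")
  list(panel = panel, record = record)
}

#' Build the longitudinal factor-analysis moment structure
#'
#' Two correlated factors (COG, FNC) per wave measured by their items;
#' marker-variable scaling (the first item of each process has its loading
#' fixed to 1).  Under strong invariance each item's loading and intercept
#' share one equality class across waves, latent means are fixed to zero
#' at wave 1 and free afterwards; under configural invariance loadings and
#' intercepts are wave-specific and all latent means are fixed to zero.
#' The 2W x 2W latent covariance is fully free (log-Cholesky) and item
#' residuals are diagonal, free per item-wave.
#'
#' @param cog_items,fnc_items item names per process (first = marker)
#' @param n_waves number of waves (>= 2)
#' @param invariance `"strong"` or `"configural"`
#' @param wave_labels labels used in manifest/latent names
#' @return a [moment_structure()] with an `lfa_map` attribute describing
#'   the item-by-wave layout
#' @export
build_lfa_structure <- function(cog_items, fnc_items, n_waves = 3,
                                invariance = c("strong", "configural"),
                                wave_labels = NULL) {
  invariance <- match.arg(invariance)
  if (n_waves < 2)
    stop("longitudinal factor analysis requires at least 2 waves")
  if (is.null(wave_labels)) wave_labels <- paste0("w", seq_len(n_waves))
  items <- c(cog_items, fnc_items)
  proc <- c(rep("COG", length(cog_items)), rep("FNC", length(fnc_items)))
  marker <- items %in% c(cog_items[1], fnc_items[1])
  J <- length(items)
  p <- J * n_waves
  m <- 2 * n_waves
  manifest <- as.vector(vapply(wave_labels, function(w)
    paste0(items, "@", w), character(J)))
  latents <- as.vector(vapply(wave_labels, function(w)
    c(paste0("COG@", w), paste0("FNC@", w)), character(2)))

  nu <- stats::setNames(numeric(p), manifest)
  Lambda <- matrix(0, p, m, dimnames = list(manifest, latents))
  alpha <- stats::setNames(numeric(m), latents)
  Psi <- diag(0.7, m) + 0.05
  diag(Psi) <- 0.7
  dimnames(Psi) <- list(latents, latents)
  Theta <- diag(0.5, p)
  dimnames(Theta) <- list(manifest, manifest)

  fr <- list(nu = integer(p), Lambda = matrix(0L, p, m),
             alpha = integer(m), Theta = matrix(0L, p, p))
  nxt <- 0L
  par_names <- character(0)
  new_par <- function(name) {
    nxt <<- nxt + 1L
    par_names[nxt] <<- name
    nxt
  }

  load_class <- stats::setNames(integer(J), items)
  int_class <- stats::setNames(integer(J), items)
  for (w in seq_len(n_waves)) {
    for (j in seq_len(J)) {
      row <- (w - 1) * J + j
      col <- (w - 1) * 2 + if (proc[j] == "COG") 1 else 2
      if (marker[j]) {
        Lambda[row, col] <- 1
      } else {
        Lambda[row, col] <- 0.7
        if (invariance == "strong") {
          if (load_class[j] == 0L)
            load_class[j] <- new_par(paste0("lambda(", items[j], ")"))
          fr$Lambda[row, col] <- load_class[j]
        } else {
          fr$Lambda[row, col] <-
            new_par(paste0("lambda(", items[j], "@", wave_labels[w], ")"))
        }
      }
      if (invariance == "strong") {
        if (int_class[j] == 0L)
          int_class[j] <- new_par(paste0("nu(", items[j], ")"))
        fr$nu[row] <- int_class[j]
      } else {
        fr$nu[row] <- new_par(paste0("nu(", items[j], "@", wave_labels[w], ")"))
      }
      fr$Theta[row, row] <-
        new_par(paste0("theta(", items[j], "@", wave_labels[w], ")"))
    }
    if (invariance == "strong" && w > 1) {
      for (f in 1:2) {
        col <- (w - 1) * 2 + f
        fr$alpha[col] <- new_par(paste0("alpha(", latents[col], ")"))
      }
    }
  }

  ms <- moment_structure(nu, Lambda, alpha, Psi, Theta, fr,
                         psi_mode = "chol", par_names = par_names)
  attr(ms, "lfa_map") <- list(items = items, proc = proc, marker = marker,
                              n_waves = n_waves, wave_labels = wave_labels,
                              cog_items = cog_items, fnc_items = fnc_items)
  ms
}

## long panel -> persons x (items x waves) wide matrix matching the structure
lfa_wide_data <- function(panel, map) {
  ids <- sort(unique(panel$id))
  p <- length(map$items) * map$n_waves
  Y <- matrix(NA_real_, length(ids), p)
  colnames(Y) <- as.vector(vapply(map$wave_labels, function(w)
    paste0(map$items, "@", w), character(length(map$items))))
  row_of <- match(panel$id, ids)
  wave_values <- sort(unique(panel$wave_year))
  for (w in seq_len(map$n_waves)) {
    sel <- as.character(panel$wave_year) == map$wave_labels[w]
    ## builder-default labels (w1, w2, ...) fall back to wave order
    if (!any(sel)) sel <- panel$wave_year == wave_values[w]
    sel[is.na(sel)] <- FALSE
    for (j in seq_along(map$items)) {
      col <- (w - 1) * length(map$items) + j
      Y[row_of[sel], col] <- panel[[map$items[j]]][sel]
    }
  }
  list(Y = Y, ids = ids)
}

#' Fit the bivariate longitudinal factor model
#'
#' Reshapes the (standardized) long item panel to persons x item-wave
#' columns and fits the structure by FIML.  The result carries the
#' standardized item-factor loadings at the reference wave and the layout
#' needed for Bartlett score extraction.
#'
#' @param panel standardized long item panel
#' @param structure a structure from [build_lfa_structure()]; the default
#'   builds a strong-invariance structure from `cog_items` / `fnc_items`
#' @param cog_items,fnc_items item names per process (used when
#'   `structure` is `NULL`; defaults match the generator's item set)
#' @param se,h1,control passed to [fit_sem()]
#' @return a `sem_fit` with classes `lfa_fit`, extra elements
#'   `std_loadings`, `wide` (persons x manifests matrix) and `map`
#' @export
fit_bivariate_lfa <- function(panel, structure = NULL,
                              cog_items = c("numeracy", "fluency",
                                            "serial7", "recall"),
                              fnc_items = c("mobility", "adl", "iadl"),
                              se = "robust", h1 = TRUE, control = list()) {
  if (is.null(structure)) {
    waves <- sort(unique(panel$wave_year))
    structure <- build_lfa_structure(cog_items, fnc_items,
                                     n_waves = length(waves),
                                     wave_labels = as.character(waves))
  }
  map <- attr(structure, "lfa_map")
  wide <- lfa_wide_data(panel, map)
  data <- missing_pattern_data(wide$Y, ids = wide$ids)
  fit <- fit_sem(structure, data, se = se, h1 = h1, control = control)
  fit$map <- map
  fit$wide <- wide
  fit$std_loadings <- lfa_std_loadings(fit)
  class(fit) <- c("lfa_fit", class(fit))
  fit
}

## standardized loadings at the reference (first) wave:
## lambda * sd(eta) / sd(y)
lfa_std_loadings <- function(fit) {
  map <- fit$map
  mats <- fit$mats
  Sigma <- mats$Lambda %*% mats$Psi %*% t(mats$Lambda) + mats$Theta
  J <- length(map$items)
  out <- data.frame(item = map$items, process = map$proc,
                    loading = NA_real_, std_loading = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(J)) {
    row <- j                       # wave-1 block
    col <- if (map$proc[j] == "COG") 1 else 2
    out$loading[j] <- mats$Lambda[row, col]
    out$std_loading[j] <- mats$Lambda[row, col] *
      sqrt(mats$Psi[col, col]) / sqrt(Sigma[row, row])
  }
  out
}

#' Extract Bartlett factor scores per person-wave
#'
#' Weighted least-squares scores
#' `(L' Theta^-1 L)^-1 L' Theta^-1 (y - nu)` computed jointly over the
#' wave's two factors using only that person-wave's observed indicators.
#' A factor with no observed indicator at a wave gets a missing score.
#' The score-error covariance `(L' Theta^-1 L)^-1` is stored per
#' missing-data pattern.
#'
#' @param fit an [fit_bivariate_lfa()] result (converged)
#' @param panel the standardized long item panel the fit used
#' @return data frame (class `factor_score_panel`) with `id`, `wave_year`,
#'   `age_years`, `cog_score`, `fnc_score`, `pattern_id`; attribute
#'   `score_error_cov` holds the per-pattern error covariance
#' @export
bartlett_scores <- function(fit, panel) {
  if (!isTRUE(fit$converged))
    warning("extracting scores from a non-converged factor model")
  map <- fit$map
  mats <- fit$mats
  J <- length(map$items)
  out <- panel[, intersect(c("id", "wave_year", "age_years"), names(panel))]
  out$cog_score <- NA_real_
  out$fnc_score <- NA_real_
  out$pattern_id <- NA_character_
  err_cov <- list()
  wave_values <- sort(unique(panel$wave_year))
  for (w in seq_len(map$n_waves)) {
    wl <- map$wave_labels[w]
    sel0 <- as.character(panel$wave_year) == wl
    if (!any(sel0)) sel0 <- panel$wave_year == wave_values[w]
    sel <- which(sel0)
    if (!length(sel)) next
    rows <- (w - 1) * J + seq_len(J)
    cols <- (w - 1) * 2 + 1:2
    Lam_w <- mats$Lambda[rows, cols, drop = FALSE]
    nu_w <- mats$nu[rows]
    th_w <- diag(mats$Theta)[rows]
    Yw <- as.matrix(panel[sel, map$items, drop = FALSE])
    key <- apply(!is.na(Yw), 1, function(z) paste(as.integer(z), collapse = ""))
    for (kv in unique(key)) {
      o <- which(strsplit(kv, "")[[1]] == "1")
      ridx <- sel[key == kv]
      pat_id <- paste0(wl, ":", kv)
      if (!length(o)) next
      L_O <- Lam_w[o, , drop = FALSE]
      have_f <- which(colSums(L_O != 0) > 0)
      if (!length(have_f)) next
      L_OF <- L_O[, have_f, drop = FALSE]
      Wi <- 1 / th_w[o]
      info <- t(L_OF) %*% (Wi * L_OF)
      info_inv <- solve(info)
      A <- info_inv %*% t(L_OF * Wi)       # (F x O) scoring weights
      Yc <- sweep(Yw[key == kv, o, drop = FALSE], 2, nu_w[o])
      sc <- Yc %*% t(A)                    # cases x factors
      if (1 %in% have_f) out$cog_score[ridx] <- sc[, match(1, have_f)]
      if (2 %in% have_f) out$fnc_score[ridx] <- sc[, match(2, have_f)]
      out$pattern_id[ridx] <- pat_id
      if (is.null(err_cov[[pat_id]])) {
        V <- matrix(NA_real_, 2, 2,
                    dimnames = list(c("COG", "FNC"), c("COG", "FNC")))
        V[have_f, have_f] <- info_inv
        err_cov[[pat_id]] <- V
      }
    }
  }
  class(out) <- c("factor_score_panel", "data.frame")
  attr(out, "score_error_cov") <- err_cov
  out
}
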