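# Ordered independent spacer-loss (OISL) model.
#
# Under OISL, spacers are inserted at the leader end of the array at relative
# rate rho and every spacer is lost independently at rate 1. Two haplotypes
# that diverged from their most recent common ancestor a time t ago each
# retain any given ancestral spacer with probability p = exp(-t): a spacer is
#   shared               with probability p^2,
#   unique to A (internal) with probability p(1-p)  (lost in B only),
#   unique to B (internal) with probability (1-p)p,
#   lost in both          with probability (1-p)^2  -- and then unobservable.
# The class likelihood therefore conditions on a spacer being observed in at
# least one lineage (divides by 1-(1-p)^2); without that term the divergence
# estimator is inconsistent. Spacers inserted after divergence and still
# surviving sit leader-ward of all shared spacers; their number per lineage
# is Poisson with mean lambda = rho * (1 - p).
#
# The pairwise distance reported is 2*t_hat, the tip-to-tip divergence.

#' Log-likelihood of a pair alignment under the ordered spacer-loss model
#'
#' @param alignment a \code{\link{align_pair}} result (or a list with
#'   elements \code{shared}, \code{internal_unique_a/b},
#'   \code{leader_unique_a/b}).
#' @param t divergence time from each tip to the common ancestor, in units
#'   of expected deletions per spacer; must be finite and >= 0.
#' @param rho insertion:deletion rate ratio; must be finite and >= 0.
#' @return the log-likelihood (\code{-Inf} where the data are impossible,
#'   e.g. unique spacers present at \code{t = 0}).
#' @export
oisl_loglik <- function(alignment, t, rho) {
  if (!is.finite(t) || t < 0) ct_error("domain_error", "t must be finite and >= 0")
  if (!is.finite(rho) || rho < 0) ct_error("domain_error", "rho must be finite and >= 0")
  n_sh <- length(alignment$shared)
  n_int <- alignment$internal_unique_a + alignment$internal_unique_b
  k_a <- alignment$leader_unique_a
  k_b <- alignment$leader_unique_b
  p <- exp(-t)
  q <- -expm1(-t)                       # 1 - p, accurate for small t
  n_obs <- n_sh + n_int                 # ancestral spacers seen in >= 1 tip
  ll <- 0
  if (n_sh > 0) ll <- ll + 2 * n_sh * log(p)
  if (n_int > 0) {
    if (q == 0) return(-Inf)
    ll <- ll + n_int * (log(p) + log(q))
  }
  # conditioning on observability: 1 - q^2 = p (1 + q), stable at large t
  if (n_obs > 0) ll <- ll - n_obs * (log(p) + log1p(q))
  lambda <- rho * q
  ll <- ll + stats::dpois(k_a, lambda, log = TRUE) +
    stats::dpois(k_b, lambda, log = TRUE)
  ll
}

# profile log-likelihood over t: for fixed t the Poisson mean maximising the
# two leader-unique terms is lambda_hat = (k_a + k_b)/2, which is attainable
# for any t > 0 (rho = lambda_hat / (1-p)), and its contribution does not
# depend on t. The shared/internal class terms alone therefore drive t_hat.
oisl_profile_loglik <- function(n_sh, n_int, t) {
  p <- exp(-t)
  q <- -expm1(-t)
  ll <- 2 * n_sh * log(p) - (n_sh + n_int) * (log(p) + log1p(q))
  if (n_int > 0) ll <- ll + ifelse(q == 0, -Inf, n_int * (log(p) + log(q)))
  ll
}

#' Fit the ordered spacer-loss model to a pair of CRISPR arrays
#'
#' Estimates, by maximum likelihood, the divergence time \code{t} between
#' two haplotypes and their most recent common ancestor and the
#' insertion:deletion rate ratio \code{rho}. The reported pairwise distance
#' is \code{2 * t_hat} (tip to tip).
#'
#' When neither array carries leader-unique spacers (the deletion-only
#' case), the maximum has closed form: \code{rho_hat = 0} and
#' \code{p_hat = 2 s / (2 s + iA + iB)} with \code{s} shared and
#' \code{iA, iB} internal-unique counts, so \code{t_hat = -log(p_hat)}
#' (the stationary point of the observability-conditioned class
#' likelihood). Otherwise \code{t} is found by bounded numerical
#' optimisation of the profile likelihood (the Poisson mean is profiled
#' analytically).
#'
#' Pairs with no shared spacers carry no information about \code{t}; they
#' receive the capped distance \code{2 * t_max} and a
#' \code{no_shared_spacers} warning.
#'
#' @param a,b \code{crispr_array} objects (or integer id vectors).
#' @param t_max upper bound for \code{t} (default 10, i.e. a retention
#'   probability of about 4.5e-5); also the cap for no-shared-spacer pairs.
#' @param tol convergence tolerance on \code{t} (default 1e-6).
#' @return an object of class \code{oisl} with components \code{t_hat},
#'   \code{rho_hat}, \code{loglik}, \code{distance} (= 2 t_hat),
#'   \code{alignment}, \code{capped}.
#' @export
oisl_pair <- function(a, b, t_max = 10, tol = 1e-6) {
  al <- if (inherits(a, "pair_alignment")) a else align_pair(a, b)
  n_sh <- length(al$shared)
  n_int <- al$internal_unique_a + al$internal_unique_b
  k_sum <- al$leader_unique_a + al$leader_unique_b
  capped <- FALSE
  if (n_sh == 0L) {
    warning(warningCondition(
      "no shared spacers: distance capped at 2 * t_max",
      class = "no_shared_spacers"))
    t_hat <- t_max
    rho_hat <- if (k_sum > 0) k_sum / 2 / (-expm1(-t_hat)) else 0
    capped <- TRUE
  } else if (n_int == 0L && k_sum == 0L) {
    t_hat <- 0
    rho_hat <- 0
  } else if (k_sum == 0L) {
    p_hat <- 2 * n_sh / (2 * n_sh + n_int)
    t_hat <- min(-log(p_hat), t_max)
    rho_hat <- 0
  } else {
    # leader-unique spacers present: profile out the Poisson mean and
    # maximise the class terms over t in (0, t_max]
    if (n_int == 0L) {
      # class terms are maximised on the boundary t -> 0, where the Poisson
      # constraint (lambda = rho (1-p) > 0) is still satisfiable for any
      # lambda by rho -> Inf; the supremum is approached, not attained.
      opt <- stats::optimize(function(t) oisl_profile_loglik(n_sh, n_int, t),
                             c(tol, t_max), maximum = TRUE, tol = tol)
      t_hat <- if (oisl_profile_loglik(n_sh, n_int, tol) >= opt$objective)
        tol else opt$maximum
    } else {
      opt <- stats::optimize(function(t) oisl_profile_loglik(n_sh, n_int, t),
                             c(0, t_max), maximum = TRUE, tol = tol)
      t_hat <- opt$maximum
    }
    rho_hat <- (k_sum / 2) / (-expm1(-t_hat))
  }
  ll <- oisl_loglik(al, t_hat, rho_hat)
  structure(
    list(t_hat = t_hat, rho_hat = rho_hat, loglik = ll,
         distance = 2 * t_hat, alignment = al, capped = capped,
         t_max = t_max),
    class = "oisl")
}

#' @export
print.oisl <- function(x, digits = 4, ...) {
  cat("Ordered spacer-loss ML fit\n")
  cat(sprintf("  t_hat    = %.*g%s\n", digits, x$t_hat,
              if (x$capped) " (capped: no shared spacers)" else ""))
  cat(sprintf("  rho_hat  = %.*g\n", digits, x$rho_hat))
  cat(sprintf("  distance = %.*g (2 * t_hat)\n", digits, x$distance))
  cat(sprintf("  logLik   = %.*g\n", digits, x$loglik))
  invisible(x)
}

#' @export
coef.oisl <- function(object, ...) {
  c(t = object$t_hat, rho = object$rho_hat)
}

#' @export
logLik.oisl <- function(object, ...) {
  structure(object$loglik, df = 2L, class = "logLik")
}

#' @export
summary.oisl <- function(object, ...) {
  al <- object$alignment
  cat(sprintf(
    "OISL pair fit: %d shared, %d/%d internal-unique, %d/%d leader-unique spacers\n",
    length(al$shared), al$internal_unique_a, al$internal_unique_b,
    al$leader_unique_a, al$leader_unique_b))
  print(object, ...)
  p <- exp(-object$t_hat)
  cat(sprintf("  implied per-spacer retention probability p = %.4g\n", p))
  invisible(object)
}

#' All-pairs OISL distance matrix
#'
#' @param haplotypes named list of \code{crispr_array} objects (>= 2).
#' @param t_max,tol passed to \code{\link{oisl_pair}}.
#' @return a symmetric numeric matrix with zero diagonal; dimnames are the
#'   haplotype labels. Pairs without shared spacers get \code{2 * t_max}.
#' @export
oisl_distance_matrix <- function(haplotypes, t_max = 10, tol = 1e-6) {
  n <- length(haplotypes)
  if (n < 2L) ct_error("invalid_array", "need at least two haplotypes")
  labels <- names(haplotypes)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      fit <- withCallingHandlers(
        tryCatch(oisl_pair(haplotypes[[i]], haplotypes[[j]],
                           t_max = t_max, tol = tol),
                 error = function(e) {
                   if (inherits(e, "collinearity_error"))
                     ct_error("collinearity_error", sprintf(
                       "pair (%s, %s): %s", labels[i], labels[j],
                       conditionMessage(e)))
                   stop(e)
                 }),
        no_shared_spacers = function(w) invokeRestart("muffleWarning"))
      d[i, j] <- d[j, i] <- fit$distance
    }
  }
  d
}

#' Write / read a square PHYLIP distance matrix
#'
#' @param d symmetric numeric matrix with dimnames.
#' @param path file path.
#' @return \code{read_phylip_dist} returns the matrix; the writer returns
#'   \code{path} invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.10g", d[i, ])), collapse = "  "), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  parts <- strsplit(trimws(lines[1L + seq_len(n)]), "[ \t]+")
  labels <- vapply(parts, `[[`, character(1), 1L)
  d <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
  dimnames(d) <- list(labels, labels)
  d
}
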