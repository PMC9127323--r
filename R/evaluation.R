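# Model evaluation: G-domain superposition, ligand RMSD (L-RMSD) in four
# atom dialects, CAPRI quality classes, and cohort hit/success-rate curves.

ATOM_DIALECTS <- list(
  backbone = c("N", "CA", "C", "O"),
  c_alpha = "CA",
  backbone_cb = c("N", "CA", "C", "O", "CB"),
  full_atom = NULL  # all atoms present in both structures
)

#' Superpose two structures on their G-domains
#'
#' Least-squares optimal rigid superposition (Kabsch) fitted on the
#' backbone atoms of M-chain residues 1-180 (the G-domains); residues or
#' atoms missing from either structure are dropped to the common resolved
#' subset. The returned rotation is proper (det = +1).
#'
#' @param model,reference `pmhc_structure` objects.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (fit RMSD on the G-domain atoms), `n_atoms`.
#' @export
superpose_gdomain <- function(model, reference) {
  pick <- function(s) {
    a <- s$atoms
    a <- a[a$chain == "M" & a$resno <= 180 &
             a$atom %in% c("N", "CA", "C", "O"), ]
    a$key <- paste(a$resno, a$atom)
    a
  }
  am <- pick(model)
  ar <- pick(reference)
  common <- intersect(am$key, ar$key)
  if (length(common) < 3) stop("fewer than 3 common G-domain atoms")
  xm <- atom_xyz(am[match(common, am$key), ])
  xr <- atom_xyz(ar[match(common, ar$key), ])
  fit <- kabsch(xm, xr)
  fit$n_atoms <- length(common)
  fit
}

#' Ligand RMSD of a model against a reference
#'
#' RMSD over corresponding peptide (P-chain) atoms after applying the
#' G-domain superposition transform to the model; no refitting is done on
#' the peptide itself. Atom correspondence is by (position, atom name)
#' over the dialect's atom set, restricted to atoms present in both
#' structures.
#'
#' @param model,reference `pmhc_structure` objects.
#' @param dialect one of `"backbone"` (N, CA, C, O; the default),
#'   `"c_alpha"`, `"backbone_cb"`, `"full_atom"`.
#' @return L-RMSD in Angstrom.
#' @export
lrmsd <- function(model, reference,
                  dialect = c("backbone", "c_alpha", "backbone_cb",
                              "full_atom")) {
  dialect <- match.arg(dialect)
  fit <- superpose_gdomain(model, reference)
  atoms <- ATOM_DIALECTS[[dialect]]
  pick <- function(s) {
    a <- s$atoms[s$atoms$chain == "P", ]
    if (!is.null(atoms)) a <- a[a$atom %in% atoms, ]
    a$key <- paste(a$resno, a$atom)
    a
  }
  pm <- pick(model)
  pr <- pick(reference)
  common <- intersect(pm$key, pr$key)
  if (length(common) == 0) stop("no corresponding peptide atoms")
  xm <- apply_transform(atom_xyz(pm[match(common, pm$key), ]), fit)
  xr <- atom_xyz(pr[match(common, pr$key), ])
  sqrt(mean(rowSums((xm - xr)^2)))
}

#' CAPRI-style quality class from an L-RMSD
#'
#' Bins: High (< 1 A), Medium (1-2 A), Acceptable (2-5 A), Incorrect
#' (>= 5 A). Bin edges are configurable.
#'
#' @param x L-RMSD values (A, non-negative).
#' @param edges upper bin edges for High/Medium/Acceptable.
#' @return factor with levels High, Medium, Acceptable, Incorrect.
#' @export
capri_class <- function(x, edges = c(1, 2, 5)) {
  if (any(x < 0)) stop("L-RMSD must be non-negative")
  cut(x, breaks = c(-Inf, edges, Inf),
      labels = c("High", "Medium", "Acceptable", "Incorrect"),
      right = FALSE)
}

#' Hit rate of one case at rank cutoff K
#'
#' A hit is a model with L-RMSD below `threshold`. The hit rate at K is
#' `n_hits(K) / M` where `n_hits(K)` counts hits among the top K ranked
#' models and M is the total number of hits for the case (a recall of the
#' achievable hits).
#'
#' @param lrmsds L-RMSD values in rank order (rank 1 first).
#' @param K rank cutoff (>= 1).
#' @param threshold hit threshold in A (default 2.0).
#' @return fraction in \[0, 1\], or `NA` if the case has no hits (M = 0).
#' @export
hit_rate <- function(lrmsds, K, threshold = 2.0) {
  if (K < 1) stop("K must be >= 1")
  hits <- lrmsds < threshold
  M <- sum(hits)
  if (M == 0) return(NA_real_)
  sum(hits[seq_len(min(K, length(hits)))]) / M
}

#' Success rate of a cohort at rank cutoff K
#'
#' A case succeeds at K iff at least one of its top K ranked models is a
#' hit; the success rate is the fraction of successful cases.
#'
#' @param cohort list of per-case L-RMSD vectors in rank order.
#' @param K rank cutoff (>= 1).
#' @param threshold hit threshold in A (default 2.0).
#' @return fraction in \[0, 1\].
#' @export
success_rate <- function(cohort, K, threshold = 2.0) {
  if (K < 1) stop("K must be >= 1")
  if (length(cohort) == 0) stop("empty cohort")
  succ <- vapply(cohort, function(lr)
    any(lr[seq_len(min(K, length(lr)))] < threshold), logical(1))
  mean(succ)
}

#' Evaluate a model run against a reference structure
#'
#' @param run a `model_run` (or a list of `pmhc_structure` models in rank
#'   order).
#' @param reference the reference `pmhc_structure`.
#' @param threshold hit threshold in A.
#' @return data.frame with one row per model: `rank`, `score`, L-RMSD in
#'   each dialect, `capri`, `hit`.
#' @export
evaluate_run <- function(run, reference, threshold = 2.0) {
  models <- if (inherits(run, "model_run")) {
    lapply(run$results, function(r) r$structure)
  } else run
  scores <- if (inherits(run, "model_run")) {
    vapply(run$results, function(r) r$score, numeric(1))
  } else rep(NA_real_, length(models))
  rows <- lapply(seq_along(models), function(i) {
    lb <- lrmsd(models[[i]], reference, "backbone")
    data.frame(rank = i, score = scores[i],
               lrmsd_backbone = lb,
               lrmsd_c_alpha = lrmsd(models[[i]], reference, "c_alpha"),
               lrmsd_backbone_cb = lrmsd(models[[i]], reference,
                                         "backbone_cb"),
               lrmsd_full_atom = lrmsd(models[[i]], reference, "full_atom"),
               capri = as.character(capri_class(lb)),
               hit = lb < threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort-level hit/success-rate curves
#'
#' @param cohort list of per-case L-RMSD vectors in rank order (e.g. the
#'   `lrmsd_backbone` columns of [evaluate_run()] outputs).
#' @param n_models maximum K for the curves.
#' @param threshold hit threshold in A.
#' @return data.frame with columns `K`, `hit_rate` (mean over cases with
#'   at least one hit), `success_rate`.
#' @export
rate_curves <- function(cohort, n_models = max(lengths(cohort)),
                        threshold = 2.0) {
  ks <- seq_len(n_models)
  hr <- vapply(ks, function(k) {
    v <- vapply(cohort, hit_rate, numeric(1), K = k, threshold = threshold)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  sr <- vapply(ks, success_rate, numeric(1), cohort = cohort,
               threshold = threshold)
  data.frame(K = ks, hit_rate = hr, success_rate = sr)
}

#' Plot hit-rate and success-rate curves
#'
#' @param curves output of [rate_curves()].
#' @return a ggplot object.
#' @export
plot_rate_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  long <- rbind(
    data.frame(K = curves$K, rate = curves$hit_rate, metric = "hit rate"),
    data.frame(K = curves$K, rate = curves$success_rate,
               metric = "success rate"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$K, y = .data$rate,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "top K ranked models", y = "rate", colour = NULL) +
    ggplot2::theme_minimal()
}
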