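#' Patient-level held-out test set and cross-validation folds
#'
#' Holds out 20% of patients as a test set, then partitions the remaining
#' patients into `n_folds` disjoint validation groups; fold k trains on the
#' other groups (an 80/20 train/validation split per fold at 5 folds). All
#' assignments are at the patient level, so no patient's nodules can appear
#' on both sides of any split, and the plan is deterministic under the seed.
#'
#' @param manifest data.frame with at least a `patient_id` column (one row
#'   per nodule), or a character vector of patient ids.
#' @param seed Integer seed.
#' @param n_folds Number of cross-validation folds.
#' @param test_frac Held-out fraction of patients.
#' @return Object of class `split_plan`: list with `test_patients` and
#'   `folds` (each a list with `train` and `val` patient vectors).
#' @export
make_splits <- function(manifest, seed = 1L, n_folds = 5L, test_frac = 0.2) {
  patients <- if (is.data.frame(manifest)) {
    unique(as.character(manifest$patient_id))
  } else {
    unique(as.character(manifest))
  }
  n <- length(patients)
  if (n < 5L) stop("need at least 5 patients to split")
  patients <- sort(patients)
  with_seed(derive_seed(seed, "split"), {
    perm <- sample(patients)
    n_test <- round(test_frac * n)
    test <- perm[seq_len(n_test)]
    rest <- perm[-seq_len(n_test)]
    grp <- rep(seq_len(n_folds), length.out = length(rest))
    folds <- lapply(seq_len(n_folds), function(k) {
      list(train = sort(rest[grp != k]), val = sort(rest[grp == k]))
    })
    structure(list(test_patients = sort(test), folds = folds,
                   n_folds = n_folds, seed = seed),
              class = "split_plan")
  })
}

#' Audit a split plan for patient leakage
#'
#' Checks that every fold's train and validation sets are disjoint, that the
#' validation groups partition the non-test patients, and that test patients
#' appear in no fold.
#'
#' @param plan A `split_plan`.
#' @return TRUE invisibly; errors on any leakage.
#' @export
audit_splits <- function(plan) {
  stopifnot(inherits(plan, "split_plan"))
  vals <- lapply(plan$folds, `[[`, "val")
  for (k in seq_along(plan$folds)) {
    f <- plan$folds[[k]]
    if (length(intersect(f$train, f$val))) {
      stop("fold ", k, ": train/val overlap")
    }
    if (length(intersect(plan$test_patients, c(f$train, f$val)))) {
      stop("fold ", k, ": test patients leak into the fold")
    }
  }
  allv <- unlist(vals)
  if (anyDuplicated(allv)) stop("validation groups overlap across folds")
  expected <- sort(unique(c(allv, plan$test_patients)))
  covered <- sort(unique(c(unlist(lapply(plan$folds, `[[`, "train")), allv,
                           plan$test_patients)))
  if (!identical(expected, covered)) stop("fold union mismatch")
  invisible(TRUE)
}

#' Rarity-upsampling sample weights
#'
#' Gives each nodule a sampling weight equal to the largest inverse frequency
#' among its observed semantic feature values (frequencies floored at
#' `freq_floor` to stop single-exemplar classes from dominating), raised to
#' `temperature`, normalized to mean 1. Nodules with no observed features get
#' the neutral weight 1. Weights are invariant to record ordering.
#' `temperature` < 1 softens the upsampling — advisable for small cohorts,
#' where full inverse-frequency weighting concentrates training on a handful
#' of rare-feature nodules.
#'
#' @param records List of `semantic_record`.
#' @param freq_floor Lower bound on any value frequency.
#' @param temperature Exponent applied to the raw inverse-frequency weights.
#' @return Numeric weight per nodule, mean 1 over non-all-missing records.
#' @export
compute_sample_weights <- function(records, freq_floor = 0.005,
                                   temperature = 1) {
  stopifnot(temperature >= 0)
  stopifnot(length(records) >= 1L)
  schema <- records[[1]]$schema
  feats <- schema_feature_names(schema)
  # frequency of each observed (feature, value) among records observing it
  freq <- list()
  for (nm in feats) {
    vals <- lapply(records, function(r) {
      v <- r$values[[nm]]
      if (length(v) == 1L && is.na(v)) return(NULL)
      if (is.logical(v)) if (v) "present" else "absent" else v
    })
    obs <- Filter(Negate(is.null), vals)
    if (!length(obs)) next
    tab <- table(unlist(obs))
    freq[[nm]] <- pmax(as.numeric(tab) / length(obs), freq_floor)
    names(freq[[nm]]) <- names(tab)
  }
  raw <- vapply(records, function(r) {
    best <- NA_real_
    for (nm in feats) {
      v <- r$values[[nm]]
      if (length(v) == 1L && is.na(v)) next
      keys <- if (is.logical(v)) (if (v) "present" else "absent") else v
      fr <- freq[[nm]][keys]
      fr <- fr[!is.na(fr)]
      if (length(fr)) best <- max(best, 1 / fr, na.rm = TRUE)
    }
    best
  }, numeric(1))
  w <- raw^temperature
  obs <- !is.na(raw)
  if (any(obs)) w[obs] <- w[obs] / mean(w[obs])
  w[!obs] <- 1
  w
}
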