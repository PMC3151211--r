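# The four leave-one-out cross-validation variants for dyadic (kinase x
# inhibitor) data. Every kinase-inhibitor pair is tested once; the variants
# differ in how much information about the test kinase and test inhibitor
# the training set may contain.
#
# Pairs are indexed row-major: pair (i, j) -> (i - 1) * n + j.

#' Split specification for dyadic LOOCV
#'
#' * `hard`: training shares neither kinase nor inhibitor with the test
#'   pair (double cold start), size (m-1)(n-1).
#' * `soft`: training holds every pair except the tested one, size mn-1.
#' * `mixed`: hard-case training plus an equal fraction of pairs containing
#'   the test inhibitor (partnered with distinct training kinases) and
#'   pairs containing the test kinase (partnered with distinct training
#'   inhibitors).
#' * `mixed_mixed`: as mixed with unequal amounts.
#'
#' Fractions convert to counts by commercial rounding against the opposite
#' dimension: a fraction f adds `round_half_up(f * m)` kinase-partner pairs
#' for the test inhibitor and `round_half_up(f * n)` inhibitor-partner
#' pairs for the test kinase (so 50% on 113 x 20 inserts 57 + 10 pairs).
#' Absolute integer counts are taken as-is.
#'
#' @param case one of `"hard"`, `"soft"`, `"mixed"`, `"mixed_mixed"`.
#' @param kinase_amount fraction in \[0,1\] or absolute count of kinase
#'   partners for the test inhibitor (mixed cases).
#' @param inhibitor_amount same for inhibitor partners of the test kinase;
#'   `mixed` requires equal fractions.
#' @param repeats averaging repeats (default 10 for mixed cases, else 1).
#' @param seed RNG seed for the random insertions.
#' @param absolute treat the amounts as absolute pair counts.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(case = c("soft", "hard", "mixed", "mixed_mixed"),
                       kinase_amount = NULL, inhibitor_amount = NULL,
                       repeats = NULL, seed = 1L, absolute = FALSE) {
  case <- match.arg(case)
  if (case %in% c("hard", "soft")) {
    assert_that(is.null(kinase_amount) && is.null(inhibitor_amount),
                "amounts apply to the mixed cases only")
    repeats <- repeats %||% 1L
  } else {
    assert_that(!is.null(kinase_amount) && !is.null(inhibitor_amount),
                "mixed cases need kinase_amount and inhibitor_amount")
    if (case == "mixed" && !absolute)
      assert_that(isTRUE(all.equal(kinase_amount, inhibitor_amount)),
                  "the mixed case uses equal kinase/inhibitor fractions")
    repeats <- repeats %||% 10L
  }
  structure(list(case = case, kinase_amount = kinase_amount,
                 inhibitor_amount = inhibitor_amount,
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 absolute = absolute),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  amt <- if (is.null(x$kinase_amount)) "" else
    sprintf(" (%s%s/%s%s)", x$kinase_amount, if (x$absolute) "" else "f",
            x$inhibitor_amount, if (x$absolute) "" else "f")
  cat(sprintf("split_spec: %s case%s, %d repeat(s), seed %d\n",
              x$case, amt, x$repeats, x$seed))
  invisible(x)
}

pair_index <- function(i, j, n) (i - 1L) * n + j
pair_ij <- function(p, n) cbind(i = ((p - 1L) %/% n) + 1L,
                                j = ((p - 1L) %% n) + 1L)

amount_to_count <- function(amount, dim_size, limit, what, absolute) {
  r <- if (absolute) {
    assert_that(amount == round(amount) && amount >= 0,
                sprintf("absolute %s amount must be a non-negative integer", what))
    as.integer(amount)
  } else {
    assert_that(amount >= 0 && amount <= 1,
                sprintf("%s fraction must lie in [0, 1]", what))
    round_half_up(amount * dim_size)
  }
  assert_that(r <= limit,
              sprintf("%s insertion count %d exceeds the %d available partners",
                      what, r, limit))
  r
}

#' Generate the m x n leave-one-out splits
#'
#' One split per kinase-inhibitor pair, in row-major order. Mixed-case
#' insertions are sampled uniformly without replacement per split, seeded
#' from `spec$seed`, and never include the test pair.
#'
#' @param m,n kinase and inhibitor counts (both >= 2).
#' @param spec a `split_spec`.
#' @return an object of class `ki_splits`: list with `m`, `n`, `spec` and
#'   `splits`, each split holding `test` (pair index) and `train` (sorted
#'   pair indices).
#' @export
make_splits <- function(m, n, spec) {
  assert_that(m >= 2 && n >= 2, "need at least 2 kinases and 2 inhibitors")
  m <- as.integer(m); n <- as.integer(n)
  r_kin <- r_inh <- 0L
  if (spec$case %in% c("mixed", "mixed_mixed")) {
    r_kin <- amount_to_count(spec$kinase_amount, m, m - 1L,
                             "kinase-partner", spec$absolute)
    r_inh <- amount_to_count(spec$inhibitor_amount, n, n - 1L,
                             "inhibitor-partner", spec$absolute)
  }
  all_pairs <- seq_len(m * n)
  ij <- pair_ij(all_pairs, n)
  set.seed(spec$seed)
  splits <- vector("list", m * n)
  for (p in all_pairs) {
    i <- ij[p, 1]; j <- ij[p, 2]
    train <- switch(spec$case,
      soft = all_pairs[-p],
      {
        hard_train <- all_pairs[ij[, 1] != i & ij[, 2] != j]
        if (spec$case == "hard") hard_train
        else {
          kin_partners <- sample(setdiff(seq_len(m), i), r_kin)
          inh_partners <- sample(setdiff(seq_len(n), j), r_inh)
          sort(c(hard_train,
                 pair_index(kin_partners, j, n),
                 pair_index(i, inh_partners, n)))
        }
      })
    splits[[p]] <- list(test = p, train = train)
  }
  structure(list(m = m, n = n, spec = spec, splits = splits),
            class = "ki_splits")
}

#' @export
print.ki_splits <- function(x, ...) {
  cat(sprintf("ki_splits: %s case, %d splits (%d x %d), training size %s\n",
              x$spec$case, length(x$splits), x$m, x$n,
              paste(unique(range(lengths(lapply(x$splits, `[[`, "train")))),
                    collapse = "-")))
  invisible(x)
}

#' Restrict a soft-case split to pairs containing the test molecules
#'
#' Keeps only the training pairs that contain the test kinase or the test
#' inhibitor: exactly (m-1) + (n-1) pairs.
#'
#' @param splits a soft-case `ki_splits`.
#' @return a `ki_splits` with restricted training sets.
#' @export
restrict_to_test_molecules <- function(splits) {
  assert_that(splits$spec$case == "soft",
              "restriction applies to soft-case splits")
  n <- splits$n
  splits$splits <- lapply(splits$splits, function(s) {
    tij <- pair_ij(s$test, n)
    ij <- pair_ij(s$train, n)
    s$train <- s$train[ij[, 1] == tij[1, 1] | ij[, 2] == tij[1, 2]]
    s
  })
  splits$spec$case <- "soft_restricted"
  splits
}

#' Assert that a split leaks no test information
#'
#' The test pair must be absent from training; in the hard case training
#' must share neither kinase nor inhibitor with the test pair. Used as the
#' evaluation loop's leakage guard.
#'
#' @param split one element of `ki_splits$splits`.
#' @param n inhibitor count.
#' @param case the split case.
#' @return TRUE invisibly; stops on leakage.
#' @export
check_split <- function(split, n, case) {
  assert_that(!(split$test %in% split$train),
              "leakage: test pair present in training set")
  if (case == "hard") {
    tij <- pair_ij(split$test, n)
    ij <- pair_ij(split$train, n)
    assert_that(!any(ij[, 1] == tij[1, 1]) && !any(ij[, 2] == tij[1, 2]),
                "leakage: hard-case training shares a molecule with the test pair")
  }
  invisible(TRUE)
}
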