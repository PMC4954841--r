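# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# one subject's rows in the long-format schema
make_subject <- function(counts, auc = 0, t = NULL, interval = NA,
                         arm = "placebo", id = 1L) {
  nv <- length(counts)
  if (is.null(t)) t <- if (all(auc == 0)) rep(0, nv) else seq_len(nv) * 168
  data.frame(subject_id = id, period_arm = arm,
             visit_day = seq_len(nv) * 168,
             t_active_days = rep_len(t, nv),
             auc_ss = rep_len(auc, nv),
             count = counts,
             interval_days = rep_len(interval, nv),
             dropout_flag = 0L)
}

# scaled-down trial design for fast fitting tests
small_design <- function(n_per = 100) {
  trial_design(arm_sizes = c(placebo = n_per, q2w = n_per, q4w = n_per),
               year1_dropout = c(placebo = round(0.09 * n_per),
                                 q2w = round(0.15 * n_per),
                                 q4w = round(0.12 * n_per)),
               year2_dropout = c(q2w = round(0.12 * n_per),
                                 q4w = round(0.16 * n_per)))
}

small_cohort <- function(n_per = 100, seed = 1, endpoint = "gd",
                         params = final_params(endpoint)) {
  simulate_trial(small_design(n_per), params, endpoint = endpoint,
                 seed = seed)
}

# pooled baseline-only dataset (every row at auc = 0)
pooled_dataset <- function(n_subj, n_visits, lam, ovdp = 0, p0 = 0,
                           family = "poisson", seed = 1) {
  withr::with_seed(seed, {
    counts <- rcount(n_subj * n_visits, lam, ovdp = ovdp, p0 = p0,
                     family = family)
    data.frame(subject_id = rep(seq_len(n_subj), each = n_visits),
               period_arm = "placebo",
               visit_day = rep(seq_len(n_visits) * 168, n_subj),
               t_active_days = 0,
               auc_ss = 0,
               count = counts,
               interval_days = NA_real_,
               dropout_flag = 0L)
  })
}

# random small subjects for Laplace/quadrature comparisons
random_subjects <- function(n = 50, seed = 3, max_visits = 4) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      nv <- sample(seq_len(max_visits), 1)
      make_subject(stats::rnbinom(nv, size = 2, mu = stats::runif(1, 0.2, 5)),
                   auc = stats::runif(1, 0, 40),
                   t = seq_len(nv) * 168, arm = "q2w")
    })
  })
}
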