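# Shared fixtures, all built in code.

# a small fully populated record table with plausible values
toy_records <- function(n = 6, region = "EU", study_id = "S1",
                        group_id = "G1") {
  data.frame(
    record_id = sprintf("%s_R%02d", study_id, seq_len(n)),
    group_id = group_id, study_id = study_id, region = region,
    breed = "Holstein", ch4_method = "chamber",
    dmi = rep(18.5, n), gei = rep(346, n), ge_diet = rep(18.7, n),
    cp = rep(16.5, n), ee = rep(3.5, n), ndf = rep(35.4, n),
    ash = rep(7.3, n), my = rep(27.0, n), mf = rep(4.1, n),
    mp = rep(3.4, n), bw = rep(611, n), ch4 = rep(369, n),
    stringsAsFactors = FALSE)
}

# records spread over several studies with varying ch4 so fits are
# non-degenerate
multi_study_records <- function(n_studies = 4, per_study = 8, seed = 42) {
  set.seed(seed)
  out <- lapply(seq_len(n_studies), function(s) {
    r <- toy_records(per_study, study_id = sprintf("S%d", s),
                     group_id = sprintf("G%d", (s + 1) %/% 2))
    r$dmi <- runif(per_study, 12, 25)
    r$ndf <- runif(per_study, 25, 45)
    r$gei <- r$dmi * r$ge_diet
    r$ch4 <- 124 + 13.3 * r$dmi + rnorm(per_study, 0, 10)
    r$my <- runif(per_study, 18, 35)
    r
  })
  do.call(rbind, out)
}

# default herd used by several suites: modest size so the suite stays fast
small_herd <- function(seed = 1, n_groups = 4, studies_per_group = 5,
                       cows_per_study = 10, ...) {
  generate_herd(sim_config(n_groups = n_groups,
                           studies_per_group = studies_per_group,
                           cows_per_study = cows_per_study,
                           seed = seed, ...))
}
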