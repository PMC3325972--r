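# Small builders used across the test files.

toy_stream <- function(n, intent, exit_time_h = seq_len(n) / (n + 1),
                       age_ok = TRUE, resident = TRUE, not_prior = TRUE,
                       driver = TRUE, drank = TRUE, refuses = FALSE,
                       unable = FALSE) {
  data.frame(exit_time_h = rep_len(exit_time_h, n),
             age_ok = rep_len(age_ok, n),
             resident = rep_len(resident, n),
             not_prior = rep_len(not_prior, n),
             driver = rep_len(driver, n),
             drank = rep_len(drank, n),
             intent = rep_len(intent, n),
             refuses = rep_len(refuses, n),
             unable = rep_len(unable, n))
}

one_outlet_frame <- function(weekday, open_h, close_h,
                             outlet_id = "ao1", cea_id = "cea1") {
  list(outlets = data.frame(outlet_id = outlet_id, cea_id = cea_id),
       schedules = data.frame(outlet_id = outlet_id, weekday = weekday,
                              open_h = open_h, close_h = close_h))
}

table1_cutoffs <- function() {
  compute_quartile_cutoffs(dui_arc_table()$prevalence_pct)
}

# tiny driver set in a single post-stratum cell
cell_drivers <- function(base_weight,
                         geo_stratum = "high_concentration",
                         sex = "men", age_group = "18-29",
                         intent = "going", cea_id = "cea1") {
  n <- length(base_weight)
  data.frame(geo_stratum = rep_len(geo_stratum, n),
             sex = rep_len(sex, n), age_group = rep_len(age_group, n),
             intent = rep_len(intent, n), cea_id = rep_len(cea_id, n),
             base_weight = base_weight)
}
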