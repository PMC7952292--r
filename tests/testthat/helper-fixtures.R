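# Small in-code fixtures shared across test files.

# a minimal well-formed survey data frame with k complete respondents
tiny_survey_df <- function(k = 3) {
  data.frame(
    id = sprintf("P%02d", seq_len(k)),
    age = rep_len(c(25L, 44L, 70L), k),
    sex = rep_len(c("female", "male"), k),
    education = rep_len(c("secondary", "higher"), k),
    economic_status = rep_len(c("181_240", "over_360"), k),
    diabetes = rep_len(c(FALSE, TRUE), k),
    mo5 = rep_len(1:3, k), sc5 = 1L, ua5 = rep_len(c(1L, 2L), k),
    pd5 = rep_len(c(2L, 1L), k), ad5 = 1L,
    mo3 = rep_len(c(1L, 1L, 2L), k), sc3 = 1L, ua3 = 1L,
    pd3 = rep_len(c(2L, 1L), k), ad3 = 1L,
    eq_vas = rep_len(c(90L, 75L, 60L), k),
    sf1 = rep_len(1:3, k),
    stringsAsFactors = FALSE)
}

tiny_survey <- function(k = 3) eq5d_survey(tiny_survey_df(k))

# survey where every respondent is at the best state on both instruments
best_state_survey <- function(k = 5) {
  df <- tiny_survey_df(k)
  for (col in c("mo5", "sc5", "ua5", "pd5", "ad5")) df[[col]] <- 1L
  for (col in c("mo3", "sc3", "ua3", "pd3", "ad3")) df[[col]] <- 1L
  eq5d_survey(df)
}
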