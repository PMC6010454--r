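fixture_md5 <- c(
  table1_clinical_scores.csv = "372341e2ae05acc2ea991c8cc7f7f6f7",
  table2_fma_subscores.csv = "c3627c9d860e65d79f6cca1cc64265bd",
  table3_contingency_metrics.csv = "b543d5dfb9fc385fd1c70b4ff05c8c0a"
)

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "bcifes")
  if (path == "") stop("fixture not found: ", name)
  got <- unname(tools::md5sum(path))
  if (got != fixture_md5[[name]]) {
    stop("fixture checksum mismatch for ", name,
         " (file corrupted or modified): ", got)
  }
  path
}

#' Bundled per-patient clinical scores of the two-arm trial
#'
#' The primary and secondary clinical outcome scores of all 27 patients
#' (14 BCI-FES, 13 sham-FES) at the pre, post and follow-up evaluations:
#' FMA-UE (0-66), modified Ashworth wrist flexor/extensor (MAS, 0-5), MRC
#' strength of the wrist extensor (0-5) and European Stroke Scale (ESS,
#' 0-100). Missing follow-up evaluations are explicit `NA`s, never zeros.
#' The fixture file is integrity-checked against a recorded checksum.
#'
#' @return A long `clinical_table` data frame: `id`, `group`, `score`,
#'   `timepoint` (`pre`/`post`/`followup`), `value`.
#' @export
load_table1 <- function() {
  wide <- utils::read.csv(fixture_path("table1_clinical_scores.csv"),
                          check.names = FALSE)
  long <- do.call(rbind, lapply(c("pre", "post", "followup"), function(tp) {
    data.frame(id = wide$id, group = wide$group, score = wide$score,
               timepoint = tp, value = wide[[tp]])
  }))
  rownames(long) <- NULL
  class(long) <- c("clinical_table", class(long))
  long
}

#' Bundled FMA-UE wrist and hand subscore summaries
#'
#' Group-level mean, standard deviation and range of the FMA-UE wrist
#' (max 10 points) and hand (max 14 points) sections at the three
#' evaluations.
#'
#' @return Data frame `group`, `section`, `timepoint`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
load_table2 <- function() {
  utils::read.csv(fixture_path("table2_fma_subscores.csv"))
}

#' Bundled contingency-metric group statistics
#'
#' Group means and standard deviations (percent) of the decoder-FES
#' contingency cells and derived metrics for the two arms, together with
#' their correlations to FMA-UE recovery. Group p-values printed only as
#' upper bounds are kept as strings (e.g. `"<1e-06"`).
#'
#' @return Data frame `metric`, `bci_mean`, `bci_sd`, `sham_mean`,
#'   `sham_sd`, `p_group`, `r_dfma`, `p_r`.
#' @export
load_table3 <- function() {
  utils::read.csv(fixture_path("table3_contingency_metrics.csv"),
                  colClasses = c(p_group = "character"))
}
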