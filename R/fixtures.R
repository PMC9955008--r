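# Embedded NCOG head/neck cancer survival data (two trial arms), the
# reference data used throughout the worked examples. Times are days from
# enrollment; censored records are flagged with status 0. The tables are
# transcribed once here and pinned by count/sum invariants in the test
# suite; the CSV interface never uses the "+"-suffix notation.

.ncog_arm_a <- function() {
  time <- c(7, 34, 42, 63, 64, 74, 83, 84, 91,
            108, 112, 129, 133, 133, 139, 140, 140, 146,
            149, 154, 157, 160, 160, 165, 173, 176, 185,
            218, 225, 241, 248, 273, 277, 279, 297, 319,
            405, 417, 420, 440, 523, 523, 583, 594, 1101,
            1116, 1146, 1226, 1349, 1412, 1417)
  status <- rep(1, 51)
  # censored: 74+ 185+ 279+ 319+ 523+ 1116+ 1226+ 1349+ 1412+
  # (523 occurs twice: one death, one censoring)
  status[c(6, 27, 34, 36, 42, 46, 48, 49, 50)] <- 0
  surv_sample(time, status)
}

.ncog_arm_b <- function() {
  time <- c(37, 84, 92, 94, 110, 112, 119, 127, 130,
            133, 140, 146, 155, 159, 169, 173, 179, 194,
            195, 209, 249, 281, 319, 339, 432, 469, 519,
            528, 547, 613, 633, 725, 759, 817, 1092, 1245,
            1331, 1557, 1642, 1771, 1776, 1897, 2023, 2146, 2297)
  status <- rep(1, 45)
  # censored: 169+ 528+ 547+ 613+ 759+ 1092+ 1245+ 1331+ 1642+ 1771+
  #           1897+ 2023+ 2146+ 2297+
  status[c(15, 28, 29, 30, 33, 35, 36, 37, 39, 40, 42, 43, 44, 45)] <- 0
  surv_sample(time, status)
}

#' Embedded NCOG study fixtures
#'
#' Head/neck cancer survival times from the two arms of the NCOG study, the
#' real reference data of the worked examples, together with the artificial
#' Covid-death time points used there (five roughly equally spaced points
#' per arm, about 10% of the arm's size).
#'
#' Arm A (chemotherapy): 51 records, 42 deaths, 9 censorings; the largest
#' time (1417) is a death, so the estimated survival distribution is
#' complete. Arm B (chemotherapy + radiation): 45 records, 31 deaths,
#' 14 censorings; the largest time (2297) is censored while the last death
#' is at 1776, so completion relocates the residual survival mass to 2297.
#'
#' @param name `"arm_a"` or `"arm_b"`.
#' @return A list of class `codmi_dataset` with elements `sample` (a
#'   [surv_sample]), `covid_times` (the default artificial Covid-death time
#'   points) and `label`.
#' @examples
#' arm_a <- ncog("arm_a")
#' nrow(arm_a$sample)    # 51
#' arm_a$covid_times     # 250 500 750 1000 1250
#' @export
ncog <- function(name = c("arm_a", "arm_b")) {
  if (!is.character(name) || !name[1] %in% c("arm_a", "arm_b")) {
    stop("unknown fixture; available fixtures: arm_a, arm_b", call. = FALSE)
  }
  name <- match.arg(name)
  out <- switch(name,
    arm_a = list(sample = .ncog_arm_a(),
                 covid_times = c(250, 500, 750, 1000, 1250),
                 label = "NCOG Arm A (chemotherapy)"),
    arm_b = list(sample = .ncog_arm_b(),
                 covid_times = c(400, 800, 1200, 1600, 2000),
                 label = "NCOG Arm B (chemotherapy + radiation)")
  )
  class(out) <- "codmi_dataset"
  out
}

#' @export
print.codmi_dataset <- function(x, ...) {
  cat(x$label, "\n")
  print(x$sample)
  cat("  default Covid-death times:", paste(x$covid_times, collapse = ", "), "\n")
  invisible(x)
}
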