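#' Study cohort characteristics
#'
#' The printed characteristics of the eight-runner study cohort the
#' synthetic generator emulates: age, body mass, height, controlled running
#' speed, running experience and sex per subject. The cohort mean speed
#' (10.6 km/h, SD 1.4) anchors the speed distribution used by
#' [generate_cohort()].
#'
#' @return data.frame with columns `subject`, `age_y`, `mass_kg`,
#'   `height_cm`, `speed_kmh`, `experience_y`, `sex`.
#' @export
#' @examples
#' round(mean(runner_characteristics()$speed_kmh), 1)  # 10.6
runner_characteristics <- function() {
  data.frame(
    subject = sprintf("S%03d", 1:8),
    age_y = c(25, 24, 23, 24, 25, 26, 23, 24),
    mass_kg = c(69, 55, 69, 64, 78, 77, 75, 82),
    height_cm = c(182, 164, 167, 168, 174, 187, 169, 188),
    speed_kmh = c(13.0, 10.5, 9.1, 9.6, 9.4, 11.6, 9.9, 11.6),
    experience_y = c(5, 3, 9, 7.5, 2, 1.5, 1.5, 6),
    sex = c("M", "F", "F", "F", "F", "M", "F", "M"))
}
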