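#' @name field_fixtures
#' @title Packaged observational tables of the grassland global-change study
#' @description
#' The field study's two printed summary tables are shipped as immutable
#' plain-CSV fixtures with md5 checksums (`inst/extdata/MANIFEST`):
#' treatment effect sizes with split-plot ANOVA p-values (Table 1) and the
#' distribution of Nitrobacter-like nxrA sequences over the three main
#' phylogenetic clusters (Table 2). These are observational values, used for
#' predicted-vs-observed comparisons and never re-derived.
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "nobsim")
  if (p == "") stop("fixture not found: ", file)
  p
}

verify_fixture <- function(file, dir = NULL) {
  p <- if (is.null(dir)) fixture_path(file) else file.path(dir, file)
  manifest_path <- if (is.null(dir)) fixture_path("MANIFEST")
                   else file.path(dir, "MANIFEST")
  manifest <- utils::read.table(manifest_path,
                                col.names = c("md5", "file"),
                                stringsAsFactors = FALSE)
  want <- manifest$md5[manifest$file == file]
  if (length(want) != 1L)
    stop("fixture '", file, "' missing from MANIFEST")
  got <- unname(tools::md5sum(p))
  if (got != want)
    stop("checksum mismatch for fixture '", file, "': expected ", want,
         ", got ", got)
  p
}

#' Load the observed treatment effect sizes (Table 1 fixture)
#'
#' @return Data.frame with columns `year` (2005/2006), `response` (PNO,
#'   Nitrobacter abundance, Nitrospira abundance), `factor` (CO2, W, N and
#'   their interactions), `percent_effect` (%; `NA` for interaction rows)
#'   and `p_value`.
#' @export
#' @examples
#' t1 <- load_table1()
#' subset(t1, year == 2005 & response == "PNO" & factor == "CO2")
load_table1 <- function() {
  d <- utils::read.csv(verify_fixture("table1_effect_sizes.csv"),
                       comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(d$p_value > 0 & d$p_value <= 1),
            all(is.finite(d$percent_effect) | is.na(d$percent_effect)))
  d
}

#' Load the observed Nitrobacter cluster composition (Table 2 fixture)
#'
#' @return Data.frame with columns `treatment`, `cluster` (A/B/C; A is the
#'   N. hamburgensis-affiliated, putatively mixotrophic cluster), `percent`,
#'   `se` and `group` (Fisher-test letter grouping).
#' @export
#' @examples
#' t2 <- load_table2()
#' subset(t2, treatment == "CO2NW" & cluster == "A")
load_table2 <- function() {
  d <- utils::read.csv(verify_fixture("table2_cluster_composition.csv"),
                       comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(d$percent >= 0 & d$percent <= 100),
            all(tapply(d$percent, d$treatment, sum) <= 100 + 1e-9))
  d
}
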