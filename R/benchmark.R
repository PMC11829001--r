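#' Load a bundled benchmark fixture table
#'
#' The package bundles the 22-case benchmark tables as tab-separated
#' fixtures: per-case DockQ components and classes for both pipelines
#' (`"table3"`), cluster ranks / total cluster counts / %near-native for
#' the highest-DockQ cluster (`"table4"`) and for the first acceptable
#' cluster (`"table5"`), stage-wise DockQ through the grid search
#' (`"table6"`), and the selected grid transforms (`"table7"`). An MD5
#' manifest guards the fixtures against silent edits.
#'
#' @param name one of `"table3"` ... `"table7"`.
#' @param check verify the file against the bundled checksum manifest.
#' @return data frame.
#' @export
read_benchmark_table <- function(name = c("table3", "table4", "table5",
                                          "table6", "table7"),
                                 check = TRUE) {
  name <- match.arg(name)
  fname <- paste0("benchmark_", name, ".tsv")
  path <- system.file("extdata", fname, package = "protern", mustWork = TRUE)
  if (check) {
    manifest <- read.delim(system.file("extdata", "benchmark_tables.md5",
                                       package = "protern", mustWork = TRUE),
                           header = FALSE, sep = "", stringsAsFactors = FALSE)
    want <- manifest$V1[manifest$V2 == fname]
    have <- unname(tools::md5sum(path))
    if (length(want) != 1 || want != have) {
      stop("fixture checksum mismatch for ", fname,
           ": the bundled table has been altered")
    }
  }
  out <- read.delim(path, stringsAsFactors = FALSE)
  if (any(!vapply(out, function(col) all(is.finite(col) | is.na(col)) ||
                    is.character(col), logical(1)))) {
    stop("malformed fixture ", fname)
  }
  out
}

.round3 <- function(x) round(x, 3)

#' Summary statistics over the benchmark fixture tables
#'
#' Recomputes, from the per-case fixture values, the aggregate quantities
#' the benchmark reports: column means and medians (3 decimals, NA cases
#' dropped), win/loss/tie counts of the grid-search pipeline versus the
#' baseline on DockQ, per-case percent improvement through the grid search
#' `(after - before) / before * 100`, and improvement-of-the-aggregates
#' for the stage table (the change of the column mean/median itself).
#' Table 7 magnitudes are summarised as means/medians of absolute values.
#'
#' @return nested list with one element per table; see Details.
#' @export
benchmark_statistics <- function() {
  t3 <- read_benchmark_table("table3")
  t4 <- read_benchmark_table("table4")
  t5 <- read_benchmark_table("table5")
  t6 <- read_benchmark_table("table6")
  t7 <- read_benchmark_table("table7")

  summarise_cols <- function(df, cols) {
    list(mean = vapply(df[cols], function(x) .round3(mean(x, na.rm = TRUE)),
                       numeric(1)),
         median = vapply(df[cols], function(x) .round3(median(x, na.rm = TRUE)),
                         numeric(1)))
  }

  num3 <- setdiff(names(t3), c("pdb_id", "botcp_class", "mega_class"))
  table3 <- summarise_cols(t3, num3)
  table3$mean_class <- dockq_class(table3$mean[["botcp_dockq"]])
  table3$mean_class_mega <- dockq_class(table3$mean[["mega_dockq"]])
  table3$wins <- sum(t3$mega_dockq > t3$botcp_dockq)
  table3$losses <- sum(t3$mega_dockq < t3$botcp_dockq)
  table3$ties <- sum(t3$mega_dockq == t3$botcp_dockq)
  table3$win_fraction <- .round3(100 * table3$wins / nrow(t3))

  table4 <- summarise_cols(t4, setdiff(names(t4), "pdb_id"))
  table5 <- summarise_cols(t5, setdiff(names(t5), "pdb_id"))

  imp <- (t6$rotated_dockq - t6$seed_dockq) / t6$seed_dockq * 100
  table6 <- summarise_cols(t6, c("seed_dockq", "translated_dockq",
                                 "rotated_dockq"))
  table6$improvement <- .round3(imp)
  table6$improvement_of_mean <- .round3(
    (mean(t6$rotated_dockq) - mean(t6$seed_dockq)) / mean(t6$seed_dockq) * 100)
  table6$improvement_of_median <- .round3(
    (median(t6$rotated_dockq) - median(t6$seed_dockq)) /
      median(t6$seed_dockq) * 100)

  axes <- c("tx", "ty", "tz", "rx", "ry", "rz")
  table7 <- list(
    mean = vapply(t7[axes], function(x) .round3(mean(abs(x))), numeric(1)),
    median = vapply(t7[axes], function(x) .round3(median(abs(x))), numeric(1)))

  list(table3 = table3, table4 = table4, table5 = table5,
       table6 = table6, table7 = table7)
}
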