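# Ingestion must classify every physical record and never lose one
# silently: accepted + quarantined == total, and every defect is
# reported with its record index and cause.

write_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("sniffing identifies each built-in dialect from its own files", {
  tb <- regular_table(10)
  f1 <- withr::local_tempfile()
  write_logger_file(tb, "wireless_long", f1)
  expect_identical(sniff_format(f1)$name, "wireless_long")

  tower <- make_deployment_series(small_geom(), quiet_cfg(1, n_days = 1))$table
  tower <- restore_series(as_tibble(tower)[tower$node_id == "tower", ], tower)
  f2 <- withr::local_tempfile()
  write_logger_file(tower, "tower_wide", f2)
  expect_identical(sniff_format(f2)$name, "tower_wide")
})

test_that("ambiguous and unmatchable files raise explicit errors, never a guess", {
  # two registered dialects consistent with the same file -> ambiguity
  clone <- logger_dialect("tower_wide_v2", ",", 2, "%Y-%m-%d %H:%M:%S",
                          layout = "wide")
  register_dialect(clone)
  withr::defer(rm("tower_wide_v2", envir = .dialects))
  tower <- make_deployment_series(small_geom(), quiet_cfg(1, n_days = 1))$table
  tower <- restore_series(as_tibble(tower)[tower$node_id == "tower", ], tower)
  f <- withr::local_tempfile()
  write_logger_file(tower, "tower_wide", f)
  err <- expect_error(sniff_format(f), class = "phenosense_ambiguous_dialect")
  expect_match(conditionMessage(err), "tower_wide")
  expect_match(conditionMessage(err), "tower_wide_v2")

  # header of the wide dialect but the column count of the long one:
  # no dialect is consistent, and the near-misses name their failed checks
  mixed <- write_lines(c("# logger export; node=x",
                         "timestamp,par_in,sw_in",
                         "2010-01-01 00:00:00,1,2,3,4"))
  err2 <- expect_error(sniff_format(mixed), class = "phenosense_no_dialect")
  expect_match(conditionMessage(err2), "fields, expected")

  empty <- write_lines("timestamp\tnode_id\tchannel\tvalue")
  err3 <- expect_error(sniff_format(empty), class = "phenosense_no_dialect")
  expect_match(conditionMessage(err3), "no data records")
})

test_that("a clean fixture ingests with zero defects and full acceptance", {
  tb <- regular_table(50)
  f <- withr::local_tempfile()
  write_logger_file(tb, "wireless_long", f)
  got <- parse_logger_file(f, "auto")
  expect_identical(got$report$counts[["total"]], 50L)
  expect_identical(got$report$counts[["accepted"]], 50L)
  expect_identical(nrow(got$report$defects), 0L)
  # provenance records the ingestion
  expect_identical(provenance(got$table)[[1]]$action, "ingest")
  expect_identical(provenance(got$table)[[1]]$user, Sys.info()[["user"]])
})

test_that("wrong column counts are quarantined with index and cause", {
  lines <- c("timestamp\tnode_id\tchannel\tvalue",
             "01/01/2010 00:00\tn1\tair_temp\t20.1",
             "01/01/2010 00:15\tn1\tair_temp\t20.2\t999",   # extra
             "01/01/2010 00:30\tn1\tair_temp",               # missing
             "01/01/2010 00:45\tn1\tair_temp\t20.4")
  f <- write_lines(lines)
  got <- parse_logger_file(f, "wireless_long")
  expect_identical(got$report$counts[["accepted"]], 2L)
  expect_identical(got$report$counts[["malformed"]], 2L)
  expect_identical(got$report$defects$record, c(2L, 3L))
  expect_match(got$report$defects$message[1], "extra column")
  expect_match(got$report$defects$message[2], "missing column")
  # no silent loss
  expect_identical(got$report$counts[["accepted"]] +
                     got$report$counts[["malformed"]],
                   got$report$counts[["total"]])
})

test_that("sentinels become explicit gaps and bad fields quarantine the record", {
  lines <- c("timestamp\tnode_id\tchannel\tvalue",
             "01/01/2010 00:00\tn1\tair_temp\tNaN",
             "01/01/2010 00:15\tn1\tair_temp\ttwenty",
             "garbage-stamp\tn1\tair_temp\t20",
             "01/01/2010 00:30\tn1\tbogus_chan\t20",
             "01/01/2010 00:45\tn1\tair_temp\t20.5")
  f <- write_lines(lines)
  got <- parse_logger_file(f, "wireless_long")
  expect_identical(got$report$counts[["accepted"]], 2L)
  expect_identical(got$table$flag, c("gap", "ok"))
  expect_true(is.na(got$table$value[1]))
  kinds <- got$report$defects$kind
  expect_setequal(kinds, c("bad_value", "bad_timestamp", "unknown_channel"))
})

test_that("timestamps running backwards are quarantined, not reordered", {
  lines <- c("timestamp\tnode_id\tchannel\tvalue",
             "01/01/2010 01:00\tn1\tair_temp\t20",
             "01/01/2010 00:45\tn1\tair_temp\t19",
             "01/01/2010 01:15\tn1\tair_temp\t21")
  f <- write_lines(lines)
  got <- parse_logger_file(f, "wireless_long")
  expect_identical(got$report$defects$kind, "timestamp_regression")
  expect_identical(got$report$defects$record, 2L)
  expect_identical(nrow(got$table), 2L)
})

test_that("injected corruption indices are reported exactly", {
  tb <- regular_table(1000)
  f <- withr::local_tempfile()
  res <- write_logger_file(tb, "wireless_long", f,
                           corruption_rate = 0.1, seed = 2024)
  got <- parse_logger_file(f, "wireless_long")
  expect_identical(sort(got$report$defects$record),
                   sort(res$corrupted$record))
  expect_identical(got$report$counts[["accepted"]] +
                     got$report$counts[["malformed"]], 1000L)
})

test_that("merging is identity with empty, additive on disjoint nodes, first-wins on conflict", {
  t1 <- regular_table(10, node = "a")
  t2 <- regular_table(10, node = "b")
  m0 <- merge_tables(list(t1, series_table()))
  expect_same_records(m0, t1)
  m1 <- merge_tables(list(t1, t2))
  expect_identical(nrow(m1), nrow(t1) + nrow(t2))

  t1b <- t1
  t1b$value[1] <- 999
  expect_message(m2 <- merge_tables(list(t1, t1b)), "first-wins")
  expect_identical(nrow(m2), nrow(t1))
  # earlier-ingested record wins
  expect_identical(m2$value[m2$timestamp == t1$timestamp[1]], t1$value[1])
  expect_identical(nrow(attr(m2, "conflicts")), nrow(t1))
})
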