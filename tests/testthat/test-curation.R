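test_that("tetravalent neutral nitrogen gains a charge; other SMILES pass through", {
  out <- fix_tetravalent_nitrogen(c("CN(C)(C)C", "CCO", "c1ccccc1"))
  # repaired string is the charged quaternary amine
  expect_equal(canonical_key(out[1]), canonical_key("C[N+](C)(C)C"))
  expect_identical(out[2], "CCO")
  expect_identical(out[3], "c1ccccc1")
})

test_that("repair turns a valence-invalid amine into a parseable structure", {
  bad <- "CC[N](C)(C)CC"
  fixed <- fix_tetravalent_nitrogen(bad)
  # validity oracle: the package's valence model before/after repair
  g_bad <- bbbalert:::parse_mol_graphs(bad)[[1]]
  g_fix <- bbbalert:::parse_mol_graphs(fixed)[[1]]
  expect_false(bbbalert:::graph_is_valid(g_bad))
  expect_true(bbbalert:::graph_is_valid(g_fix))
  # cross-check with an independent strict SMILES parser when available
  py <- Sys.which("python")
  if (nzchar(py)) {
    script <- paste(
      "import sys",
      "from rdkit import Chem",
      "for s in sys.argv[1:]:",
      "    print(int(Chem.MolFromSmiles(s) is not None))",
      sep = "\n"
    )
    res <- suppressWarnings(system2(py, c("-c", shQuote(script), shQuote(bad), shQuote(fixed)),
      stdout = TRUE, stderr = FALSE
    ))
    if (length(res) == 2L) {
      expect_identical(res, c("0", "1"))
    }
  }
})

test_that("canonical keys unify acid, carboxylate, salt, and atom-order respellings", {
  keys <- canonical_key(c(
    "CC(=O)O", "CC(=O)[O-]", "CC(=O)[O-].[Na+]",
    "OCC", "CCO",
    "c1ccccc1CN", "NCc1ccccc1"
  ))
  expect_identical(keys[1], keys[2])
  expect_identical(keys[1], keys[3])
  expect_identical(keys[4], keys[5])
  expect_identical(keys[6], keys[7])
  # acid and alcohol do not collapse
  expect_false(keys[1] == keys[4])
  expect_error(canonical_key("not-a-smiles"), class = "bbbalert_config_error")
  expect_true(is.na(canonical_key("not-a-smiles", strict = FALSE)))
})

test_that("deduplicate keeps first occurrences and removes label conflicts whole", {
  rec <- function(id, smi, label, key) {
    tibble::tibble(record_id = id, name = id, smiles = smi, label = label, key = key)
  }
  # same key, consistent labels -> one kept
  d <- deduplicate(dplyr::bind_rows(rec("a", "CCO", 1L, "k1"), rec("b", "OCC", 1L, "k1")))
  expect_equal(nrow(d$records), 1L)
  expect_identical(d$records$record_id, "a")
  expect_equal(d$report$n_duplicates_removed, 1L)
  # same key, conflicting labels -> all removed
  d2 <- deduplicate(dplyr::bind_rows(rec("a", "CCO", 1L, "k1"), rec("b", "OCC", 0L, "k1")))
  expect_equal(nrow(d2$records), 0L)
  expect_equal(d2$report$n_inconsistent_records_removed, 2L)
  # consistent triplicate -> one kept, counted as a triplicate group
  d3 <- deduplicate(dplyr::bind_rows(
    rec("a", "CCO", 1L, "k1"), rec("b", "OCC", 1L, "k1"), rec("c", "CCO", 1L, "k1")
  ))
  expect_equal(nrow(d3$records), 1L)
  expect_equal(d3$report$n_duplicates_removed, 2L)
  expect_equal(d3$report$n_triplicate_groups, 1L)
})

test_that("curate applies repair, keying and deduplication in order", {
  tab <- data.frame(
    num = 1:4, name = letters[1:4], p_np = c(1, 1, 1, 0),
    smiles = c("CN(C)(C)C", "CCO", "OCC", "c1ccccc1")
  )
  cur <- curate(tab)
  # hand trace: invalid-N repaired (kept), CCO/OCC deduplicated, benzene kept
  expect_equal(cur$report$n_output, 3L)
  expect_equal(cur$report$n_nitrogen_fixed, 1L)
  expect_equal(cur$report$n_duplicates_removed, 1L)
  expect_equal(cur$report$n_unparseable_dropped, 0L)
})

test_that("curate handles empty tables and missing columns", {
  empty <- curate(data.frame(num = integer(0), name = character(0),
    p_np = integer(0), smiles = character(0)
  ))
  expect_equal(empty$report$n_input, 0L)
  expect_equal(empty$report$n_output, 0L)
  expect_error(curate(data.frame(x = 1)), class = "bbbalert_config_error")
  expect_error(
    curate(data.frame(num = 1, name = "a", p_np = 2, smiles = "CCO")),
    class = "bbbalert_config_error"
  )
})

test_that("curation is conservative, idempotent, and leaves no defects behind", {
  for (seed in c(11L, 23L)) {
    fx <- make_corrupt_table(seed = seed)
    cur <- curate(fx$table)
    r <- cur$report
    # injected defect counts are reported exactly
    expect_equal(r$n_input, fx$n_input)
    expect_equal(r$n_nitrogen_fixed, fx$n_nitrogen_fixed)
    expect_equal(r$n_unparseable_dropped, fx$n_unparseable_dropped)
    expect_equal(r$n_duplicates_removed, fx$n_duplicates_removed)
    expect_equal(r$n_inconsistent_records_removed, fx$n_inconsistent_records_removed)
    # conservation identity
    expect_equal(
      r$n_output,
      r$n_input - r$n_unparseable_dropped - r$n_duplicates_removed -
        r$n_inconsistent_records_removed
    )
    # keys pairwise distinct
    expect_false(anyDuplicated(cur$records$key) > 0)
    # no neutral tetravalent nitrogen survives (re-scan outputs)
    graphs <- bbbalert:::parse_mol_graphs(cur$records$smiles)
    expect_true(all(vapply(graphs, function(g) {
      !is.null(g) && !any(g$elem == "N" & g$charge == 0L & g$order_sum >= 4L)
    }, logical(1))))
    # idempotence: curating the curated dataset changes nothing
    cur2 <- curate(cur)
    expect_identical_tables(cur$records, cur2$records)
    expect_equal(cur2$report$n_duplicates_removed, 0L)
    expect_equal(cur2$report$n_output, cur$report$n_output)
  }
})

test_that("curated datasets round-trip through the CSV dialect", {
  fx <- make_corrupt_table(seed = 5L)
  cur <- curate(fx$table)
  csv <- tempfile(fileext = ".csv")
  rep <- tempfile(fileext = ".json")
  write_curated(cur, csv, rep)
  back <- read_bbbp_csv(csv)
  expect_equal(nrow(back), cur$report$n_output)
  expect_identical(back$smiles, cur$records$smiles)
  j <- jsonlite::read_json(rep)
  expect_equal(j$n_output, cur$report$n_output)
  # broom-style accessors
  expect_s3_class(tidy(cur), "tbl_df")
  expect_equal(glance(cur)$n_input, cur$report$n_input)
})
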