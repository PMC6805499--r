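write_simple_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

gds <- function(id, domains, group = "anaerobe") {
  structure(list(genome_id = id, group = group, domains = sort(domains),
                 gene_count = length(domains), n_skipped = 0L),
            class = "genome_domain_set")
}

test_that("simple_tsv loader de-duplicates to genome-level presence", {
  path <- write_simple_tsv(data.frame(
    genome_id = "g1",
    gene_id = c("a", "b", "c", "d", "e"),
    domain_id = c("IPR000890", "IPR000890", "IPR000890", "IPR000001",
                  "IPR000002")))
  g <- load_domain_annotations(path, genome_id = "g1", group = "aerobe")
  expect_identical(g$domains, c("IPR000001", "IPR000002", "IPR000890"))
  expect_identical(g$gene_count, 5L)
  bad <- write_simple_tsv(data.frame(genome_id = "g", gene = "x",
                                     dom = "y"))
  expect_error(load_domain_annotations(bad), "columns")
})

test_that("InterProScan dialect takes column 12, skipping unmapped rows", {
  mk_row <- function(protein, acc) {
    paste(c(protein, "md5", "100", "Pfam", "PF00001", "desc", "1", "99",
            "1e-10", "T", "15-03-2015", acc, "name", "-", "-"),
          collapse = "\t")
  }
  path <- tempfile(fileext = ".tsv")
  writeLines(c(mk_row("p1", "IPR000890"), mk_row("p2", "IPR000890"),
               mk_row("p3", "IPR000890"), mk_row("p4", "-"),
               mk_row("p5", "IPR003538")), path)
  g <- load_domain_annotations(path, dialect = "interproscan_tsv",
                               genome_id = "g1", group = "anaerobe")
  expect_identical(g$domains, c("IPR000890", "IPR003538"))
  expect_identical(g$n_skipped, 1L)
  # truncated row: skip by default, error with line number in strict mode
  trunc <- tempfile(fileext = ".tsv")
  writeLines(c(mk_row("p1", "IPR000890"), "p2\tonly\tthree"), trunc)
  g2 <- load_domain_annotations(trunc, dialect = "interproscan_tsv",
                                genome_id = "g1", group = "anaerobe")
  expect_identical(g2$domains, "IPR000890")
  expect_error(
    load_domain_annotations(trunc, dialect = "interproscan_tsv",
                            genome_id = "g1", group = "anaerobe",
                            strict = TRUE),
    "line 2")
})

test_that("core and exclusive-core set algebra honours the edge cases", {
  a <- gds("a", c("IPR1", "IPR2", "IPR3"))
  b <- gds("b", c("IPR2", "IPR3", "IPR4"))
  disjoint <- gds("d", c("IPR9"))
  expect_identical(core_domains(list(a)), a$domains)
  expect_identical(core_domains(list(a, b)), c("IPR2", "IPR3"))
  expect_identical(core_domains(list(a, disjoint)), character(0))
  expect_error(core_domains(list()), "empty")
  expect_identical(exclusive_core(list(a), list(a)), character(0))
  expect_identical(exclusive_core(list(a, b), list(disjoint)),
                   c("IPR2", "IPR3"))
  expect_error(exclusive_core(list(a), list()), "empty")
})

test_that("exclusive core is monotone under panel growth", {
  set.seed(42)
  pool <- sprintf("IPR%06d", 1:300)
  panels <- lapply(1:8, function(i) {
    gds(paste0("g", i), sample(pool, 150))
  })
  tgt <- panels[1:3]; bgd <- panels[4:6]
  base <- exclusive_core(tgt, bgd)
  grown_t <- exclusive_core(c(tgt, panels[7]), bgd)
  grown_b <- exclusive_core(tgt, c(bgd, panels[8]))
  expect_true(all(grown_t %in% base))
  expect_true(all(grown_b %in% base))
  # and equals the brute-force presence/absence oracle
  expect_identical(base, oracle_exclusive_core(tgt, bgd))
})

test_that("categorization defaults unmapped accessions to unknown_function",
{
  empty <- categorize_domains(character())
  expect_identical(unname(empty$counts), c(0L, 0L, 0L))
  expect_identical(empty$total, 0L)
  res <- categorize_domains(c("IPR000890", "IPR003538", "IPR999999"))
  expect_identical(unname(res$counts["atp_generation"]), 1L)
  expect_identical(unname(res$counts["other"]), 1L)
  expect_identical(unname(res$counts["unknown_function"]), 1L)
  expect_identical(res$n_unmapped, 1L)
  expect_identical(sum(res$counts), res$total)
  expect_error(categorize_domains("IPR1", c(IPR1 = "nonsense")),
               "outside")
})

test_that("the shipped map assigns the named accessions to ATP generation",
{
  m <- default_category_map()
  expect_identical(unname(m[c("IPR000890", "IPR012833", "IPR012840")]),
                   rep("atp_generation", 3))
})

test_that("presence/absence matrix and shortlist report are consistent", {
  a <- gds("a", c("IPR1", "IPR2"))
  b <- gds("b", c("IPR2"), group = "aerobe")
  m <- presence_absence_matrix(list(a, b))
  expect_identical(dim(m), c(2L, 2L))
  expect_true(m["a", "IPR1"] && !m["b", "IPR1"])
  path <- tempfile(fileext = ".tsv")
  write_shortlist_report("IPR1", list(a, b), path)
  rep <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_identical(rep$accession, "IPR1")
  expect_identical(rep$a, 1L)
  expect_identical(rep$b, 0L)
})
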