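make_manifest <- function() {
  genome_manifest(c("a", "b", "c", "d", "e", "f"),
                  c("G1", "G1", "G2", "G2", "G3", "G3"),
                  c(100L, 100L, 200L, 150L, 150L, 120L))
}

test_that("parse_hits deduplicates, drops self hits, and handles empties", {
  m <- make_manifest()
  h <- parse_hits(data.frame(query_id = c("a", "a", "a"),
                             subject_id = c("b", "b", "a"),
                             e_value = c(1e-30, 1e-10, 0),
                             aln_length = c(100L, 40L, 150L)), m)
  expect_equal(nrow(h), 1L)
  expect_equal(h$e_value, 1e-30)
  expect_equal(h$aln_length, 100L)

  expect_equal(nrow(parse_hits(data.frame(query_id = character(),
                                          subject_id = character(),
                                          e_value = numeric(),
                                          aln_length = integer()), m)), 0L)
  empty_file <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty_file)
  expect_equal(nrow(parse_hits(empty_file, m)), 0L)
})

test_that("parse_hits errors name the offending id or line", {
  m <- make_manifest()
  expect_error(parse_hits(data.frame(query_id = "a", subject_id = "zz",
                                     e_value = 1e-30, aln_length = 10L), m),
               "zz")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("a", "b", "100.0", "90", 0, 0, 1, 90, 1, 90,
                       "1e-30", "200"), collapse = "\t"),
               paste(c("a", "c", "100.0", "oops", 0, 0, 1, 90, 1, 90,
                       "1e-30", "200"), collapse = "\t")), bad)
  expect_error(parse_hits(bad, m), "line.*2")
})

test_that("parse_hits reads BLAST outfmt-6 files with the default columns", {
  m <- make_manifest()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("a", "b", "99.0", "95", 1, 0, 1, 95, 1, 95,
                     "4.5e-50", "180"), collapse = "\t"), f)
  h <- parse_hits(f, m)
  expect_equal(h$query_id, "a")
  expect_equal(h$e_value, 4.5e-50)
  expect_equal(h$aln_length, 95L)
})

test_that("build_links enforces all four conditions strictly", {
  m <- make_manifest()
  crit <- link_criteria(e_cut = 1e-20, f_min = 0.7)
  mk <- function(e_ab, e_ba, len_ab, len_ba, q = "a", s = "b") {
    parse_hits(data.frame(query_id = c(q, s), subject_id = c(s, q),
                          e_value = c(e_ab, e_ba),
                          aln_length = c(len_ab, len_ba)), m)
  }
  # one E-value above the cutoff: no link even though the other passes
  expect_equal(nrow(build_links(mk(1e-25, 1e-19, 80L, 80L), m, crit)), 0L)
  # all conditions pass (lengths 100/100, fraction 0.8 > 0.7)
  expect_equal(nrow(build_links(mk(1e-30, 1e-30, 80L, 80L), m, crit)), 1L)
  # alignment shorter than f_min of the longer sequence (a=100, c=200)
  expect_equal(nrow(build_links(mk(1e-30, 1e-30, 90L, 90L, q = "a", s = "c"),
                                m, crit)), 0L)
  # strictness at the boundary: E == e_cut and fraction == f_min both fail
  expect_equal(nrow(build_links(mk(1e-20, 1e-30, 80L, 80L), m, crit)), 0L)
  expect_equal(nrow(build_links(mk(1e-30, 1e-30, 70L, 70L), m, crit)), 0L)
  # one-directional hit never links
  one_dir <- parse_hits(data.frame(query_id = "a", subject_id = "b",
                                   e_value = 1e-40, aln_length = 90L), m)
  expect_equal(nrow(build_links(one_dir, m, crit)), 0L)
})

test_that("single_link_clusters partitions all genes deterministically", {
  m <- make_manifest()
  links <- data.table::data.table(gene1 = c("a", "b", "d"),
                                  gene2 = c("b", "c", "e"))
  cl <- single_link_clusters(m, links)
  expect_setequal(cl$gene_id, m$gene_id)
  expect_equal(anyDuplicated(cl$gene_id), 0L)
  sizes <- sort(table(cl$cluster_id))
  expect_equal(unname(sort(as.integer(sizes))), c(1L, 2L, 3L))
  # singleton f has its own cluster
  expect_equal(sum(cl$cluster_id == cl$cluster_id[cl$gene_id == "f"]), 1L)
  # no links at all: every gene a singleton
  cl0 <- single_link_clusters(m, links[0])
  expect_equal(length(unique(cl0$cluster_id)), nrow(m))
  # identical input -> identical output
  expect_identical(cl, single_link_clusters(m, links))
})

test_that("a chain across genomes forms one cluster with g=4, k=4, nbar=1", {
  m <- genome_manifest(c("a", "b", "c", "d"), c("G1", "G2", "G3", "G4"),
                       rep(100L, 4))
  links <- data.table::data.table(gene1 = c("a", "b", "c"),
                                  gene2 = c("b", "c", "d"))
  s <- cluster_summary(single_link_clusters(m, links))
  expect_equal(nrow(s), 1L)
  expect_equal(s$g, 4L)
  expect_equal(s$k, 4L)
  expect_equal(s$nbar, 1)
})

test_that("clusters match the brute-force closure oracle on random graphs", {
  set.seed(71)
  for (i in 1:30) {
    case <- random_graph_case(sample(5:120, 1))
    cl <- single_link_clusters(case$manifest, case$links)
    got <- cluster_labels(cl)[case$genes]
    want <- closure_membership(case$genes, case$links)
    expect_equal(adjusted_rand(got, want), 1)
    expect_equal(sum(cluster_summary(cl)$g), nrow(case$manifest))
  }
})

test_that("relaxing the link criteria never increases the cluster count", {
  pan <- generate_planted_pangenome(n_genomes = 6, n_clusters = 80,
                                    noise_frac = 1, seed = 99)
  # re-grade the same hit table under increasingly permissive cutoffs
  e_grid <- c(1e-150, 1e-100, 1e-50, 1e-21, 1e-5)
  counts <- vapply(e_grid, function(ec) {
    crit <- link_criteria(e_cut = ec, f_min = pan$f_min)
    cl <- single_link_clusters(pan$manifest,
                               build_links(pan$hits, pan$manifest, crit))
    length(unique(cl$cluster_id))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  f_grid <- c(0.95, 0.8, 0.5, 0.2)
  counts_f <- vapply(f_grid, function(fm) {
    crit <- link_criteria(e_cut = pan$e_cut, f_min = fm)
    cl <- single_link_clusters(pan$manifest,
                               build_links(pan$hits, pan$manifest, crit))
    length(unique(cl$cluster_id))
  }, 0L)
  expect_true(all(diff(counts_f) <= 0))
})

test_that("build_links errors when a hit references a gene without a length", {
  m <- make_manifest()
  h <- data.table::data.table(query_id = c("a", "zz"), subject_id = c("zz", "a"),
                              e_value = c(1e-40, 1e-40),
                              aln_length = c(90L, 90L))
  expect_error(build_links(h, m, link_criteria()), "zz")
})
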