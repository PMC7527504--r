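test_that("MSN handles the elementary cases", {
  two <- minimum_spanning_network(
    alignment(c("h1", "h2"), c("AAAA", "AAAT")))
  expect_equal(nrow(two$edges), 1L)
  expect_equal(two$edges$weight, 1L)
  star <- minimum_spanning_network(
    alignment(c("c", "x", "y"), c("AAA", "AAT", "TAA")))
  expect_equal(nrow(star$edges), 2L)
  expect_true(all(star$edges$weight == 1L))
  one <- minimum_spanning_network(alignment(c("a", "b"), c("AA", "AA")))
  expect_equal(nrow(one$nodes), 1L)
  expect_equal(one$nodes$multiplicity, 2L)
  expect_equal(nrow(one$edges), 0L)
  tri <- minimum_spanning_network(
    alignment(c("x1", "x2", "x3"), c("AAG", "AGA", "GAA")))
  expect_equal(nrow(tri$edges), 3L)            # all-MSTs union: triangle
})

test_that("MSN equals the union of all minimum spanning trees (oracle)", {
  set.seed(17)
  for (r in 1:6) {
    n <- sample(4:6, 1)
    seqs <- replicate(n, paste(sample(c("A", "T"), 8, TRUE), collapse = ""))
    if (anyDuplicated(seqs)) next
    net <- minimum_spanning_network(alignment(paste0("h", 1:n), seqs))
    d <- slocuspop:::hamming_matrix(seqs)
    want <- oracle_mst_union(d)
    got <- cbind(match(net$edges$from, paste0("h", 1:n)),
                 match(net$edges$to, paste0("h", 1:n)))
    got <- t(apply(got, 1, sort))
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want$edges))
    expect_equal(net$total_mutation_length, as.integer(want$weight))
  }
})

test_that("median joining is a fixed point on tree-like haplotypes", {
  a <- alignment(paste0("h", 1:3), c("AAA", "AAT", "ATT"))
  mj <- median_joining_network(a)
  msn <- minimum_spanning_network(a)
  expect_equal(mj$edges, msn$edges)
  expect_equal(sum(mj$nodes$type == "median"), 0L)
})

test_that("median vectors shorten the network where a Steiner point exists", {
  a <- alignment(paste0("t", 1:3), c("AAAAA", "AATTT", "TTTAA"))
  mj <- median_joining_network(a)
  msn <- minimum_spanning_network(a)
  expect_equal(sum(mj$nodes$type == "median"), 1L)
  expect_equal(mj$nodes$seq[mj$nodes$type == "median"], "AATAA")
  expect_lt(mj$total_mutation_length, msn$total_mutation_length)
  # four-haplotype cycle: all observed nodes present, cost <= MST cost
  b <- alignment(paste0("h", 1:4), c("AAA", "ATA", "AAT", "ATT"))
  mjb <- median_joining_network(b)
  expect_true(all(paste0("h", 1:4) %in% mjb$nodes$id))
  expect_lte(mjb$total_mutation_length,
             minimum_spanning_network(b)$total_mutation_length)
})

test_that("MJ network keeps an observed-haplotype MST as a subgraph", {
  set.seed(23)
  for (r in 1:4) {
    seqs <- unique(replicate(6, paste(sample(c("A", "C", "T"), 10, TRUE),
                                      collapse = "")))
    a <- alignment(paste0("h", seq_along(seqs)), seqs)
    mj <- median_joining_network(a, epsilon = 0)
    obs_msn <- minimum_spanning_network(a)
    key <- function(e) apply(e, 1, function(x)
      paste(sort(c(x[["from"]], x[["to"]])), collapse = "|"))
    expect_true(all(key(obs_msn$edges) %in% key(mj$edges)))
    expect_true(all(a$id %in% mj$nodes$id))
    expect_lte(mj$total_mutation_length, obs_msn$total_mutation_length)
    expect_true(all(mj$nodes$multiplicity[mj$nodes$type == "median"] == 0))
  }
})

test_that("non-ACGT states at variable sites are rejected", {
  expect_error(median_joining_network(
    alignment(c("a", "b"), c("AANA", "AATA"))), "A/C/G/T")
})

test_that("rho is the mean mutational distance and age = rho / mu", {
  edges <- data.frame(from = c("anc", "anc", "b"),
                      to = c("a", "b", "c"),
                      weight = c(1L, 2L, 1L))
  nodes <- data.frame(id = c("anc", "a", "b", "c"),
                      seq = NA, multiplicity = c(1L, 1L, 1L, 1L),
                      members = "", type = "observed")
  net <- structure(list(nodes = nodes, edges = edges), class = "hap_network")
  r <- rho_age(net, "anc", c("a", "b", "c"))
  expect_equal(r$rho, 2)                       # distances 1, 2, 3
  expect_equal(r$age_years, 2000)
  expect_equal(rho_age(net, "anc", "anc")$rho, 0)
  expect_equal(rho_age(net, "anc", c("a", "b", "c"), mu = 1e-3)$age_years,
               r$rho * 1000)
  expect_error(rho_age(net, "anc", "zz"), "not in network")
  # rho = 25.5 mutational units converts to 25,500 years at mu = 1e-3
  long <- structure(list(
    nodes = data.frame(id = c("anc", "x"), seq = NA, multiplicity = 1L,
                       members = "", type = "observed"),
    edges = data.frame(from = "anc", to = "x", weight = 25.5)),
    class = "hap_network")
  expect_equal(rho_age(long, "anc", "x")$age_years, 25500)
})

test_that("doubling every mutation doubles rho (scaling property)", {
  seqs <- c("AAAA", "AATT", "TTTT")
  a1 <- alignment(paste0("h", 1:3), seqs)
  a2 <- alignment(paste0("h", 1:3), paste0(seqs, seqs))  # duplicate columns
  n1 <- minimum_spanning_network(a1)
  n2 <- minimum_spanning_network(a2)
  r1 <- rho_age(n1, "h1", c("h2", "h3"))
  r2 <- rho_age(n2, "h1", c("h2", "h3"))
  expect_equal(r2$rho, 2 * r1$rho)
})

test_that("network writers round-trip through TSV and emit GraphML", {
  a <- alignment(paste0("h", 1:4), c("AAA", "ATA", "AAT", "ATT"))
  net <- median_joining_network(a)
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".graphml")
  write_network_tsv(net, ep, np)
  back <- read_network_tsv(ep, np)
  expect_equal(nrow(back$edges), nrow(net$edges))
  expect_equal(back$total_mutation_length, net$total_mutation_length)
  write_network_graphml(net, gp)
  expect_true(any(grepl("graphml", readLines(gp, n = 5))))
})
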