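test_that("network merge takes the union with best-profile attributes", {
  n1 <- net_from("a", "b", r = 0.5, p = 1e-3, id = "n1")
  n2 <- cerna_network(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                                 r = c(0.9, 0.4), p = c(1e-6, 1e-2),
                                 q = 1e-2, n_shared = 3L), "n2")
  merged <- merge_networks(list(n1, n2), "m")
  expect_equal(nrow(merged$edges), 2L)
  # a-b keeps the n2 attributes (smaller p)
  ab <- merged$edges[merged$edges$gene_a == "a" & merged$edges$gene_b == "b", ]
  expect_equal(ab$r, 0.9)
  # disjoint networks simply add up
  d1 <- net_from("a", "b")
  d2 <- net_from("c", "d")
  expect_equal(nrow(merge_networks(list(d1, d2))$edges), 2L)
})

test_that("profile networks merge into one network per disease", {
  st <- small_study(seed = 33, n_profiles = 6, n_diseases = 3)
  cand <- candidate_pairs(st$interactions)
  nets <- lapply(st$profiles, build_profile_network, candidates = cand)
  diseases <- vapply(st$profiles, `[[`, character(1), "disease")
  dnets <- merge_by_disease(nets, diseases)
  expect_length(dnets, 3L)
  expect_true(all(vapply(dnets, `[[`, character(1), "level") == "disease"))
})

test_that("Simpson index has the overlap-coefficient semantics", {
  expect_equal(simpson_index(c("a", "b", "c"), c("b", "c", "d", "e")), 2 / 3)
  expect_equal(simpson_index(c("x", "y"), c("x", "y")), 1)
  expect_equal(simpson_index(c("x"), c("y")), 0)
  expect_equal(simpson_index(character(0), c("a")), 0)
  expect_equal(simpson_index(character(0), character(0)), 0)
})

test_that("similarity matrix is symmetric with unit diagonal", {
  n1 <- net_from(c("a", "c"), c("b", "d"), id = "n1")
  n2 <- net_from(c("a", "e"), c("b", "f"), id = "n2")  # shares half of n1
  n3 <- net_from("g", "h", id = "n3")
  res <- network_similarity_matrix(list(n1 = n1, n2 = n2, n3 = n3))
  expect_equal(res$sim, t(res$sim))
  expect_equal(diag(res$sim), c(n1 = 1, n2 = 1, n3 = 1))
  expect_equal(res$sim["n1", "n2"], 0.5)
  expect_equal(res$sim["n1", "n3"], 0)
  expect_true(all(res$sim >= 0 & res$sim <= 1))
})

test_that("permutation p-value reaches its floor for identical networks", {
  universe <- paste(sprintf("g%03d", 1:200), sprintf("h%03d", 1:200),
                    sep = "\t")
  edges <- data.frame(gene_a = sprintf("g%03d", 1:30),
                      gene_b = sprintf("h%03d", 1:30),
                      r = 0.5, p = 1e-4, q = 1e-4, n_shared = 3L)
  n1 <- cerna_network(edges, "n1")
  n2 <- cerna_network(edges, "n2")
  res <- network_similarity_matrix(list(n1 = n1, n2 = n2),
                                   n_permutations = 99, universe = universe,
                                   seed = 7)
  expect_equal(res$p["n1", "n2"], 1 / 100)
})

test_that("edge occurrence counts conserve the total edge mass", {
  n1 <- net_from(c("a", "c"), c("b", "d"), id = "n1")
  n2 <- net_from(c("a", "e"), c("b", "f"), id = "n2")
  res <- edge_profile_counts(list(n1, n2))
  expect_equal(sum(res$counts$count), nrow(n1$edges) + nrow(n2$edges))
  expect_equal(res$counts$count[res$counts$gene_a == "a"], 2L)
  expect_equal(unname(res$histogram["1"]), 2L)
})

test_that("core extraction follows the occurrence threshold strictly", {
  base <- function(i) {
    e <- data.frame(gene_a = character(), gene_b = character())
    if (i <= 16) e <- rbind(e, data.frame(gene_a = "c1", gene_b = "c2"))
    if (i <= 15) e <- rbind(e, data.frame(gene_a = "d1", gene_b = "d2"))
    if (i == 1) e <- rbind(e, data.frame(gene_a = "s1", gene_b = "s2"))
    cerna_network(e, sprintf("n%02d", i))
  }
  nets <- lapply(1:21, base)
  core <- extract_core_network(nets, min_profiles = 16)
  expect_equal(keys_of(core), "c1\tc2")
  # threshold 1 recovers the union
  expect_equal(sort(keys_of(extract_core_network(nets, 1))),
               sort(c("c1\tc2", "d1\td2", "s1\ts2")))
  expect_error(extract_core_network(nets, 22), "exceeds")
  # no shared edges -> empty core
  disjoint <- lapply(1:3, function(i) {
    net_from(sprintf("u%d", i), sprintf("v%d", i), id = paste0("d", i))
  })
  expect_equal(nrow(extract_core_network(disjoint, 2)$edges), 0L)
})

test_that("core shrinks monotonically as the threshold grows", {
  st <- small_study(seed = 35)
  cand <- candidate_pairs(st$interactions)
  nets <- lapply(st$profiles, build_profile_network, candidates = cand,
                 candidates_only = FALSE)
  sizes <- vapply(1:6, function(k) {
    nrow(extract_core_network(nets, k)$edges)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  merged <- merge_networks(nets, "g", "global")
  expect_true(all(keys_of(extract_core_network(nets, 4)) %in% keys_of(merged)))
})

test_that("hub identification takes the top decile with inclusive ties", {
  # 100 nodes with distinct degrees: star sizes 1..100 via a hub construction
  edges <- do.call(rbind, lapply(1:13, function(s) {
    data.frame(gene_a = sprintf("hub%02d", s),
               gene_b = sprintf("hub%02d_leaf%02d", s, 1:s))
  }))
  nw <- cerna_network(edges, "stars")
  deg <- network_degrees(nw)
  hubs <- identify_hubs(nw, top_frac = 0.10)
  k <- ceiling(0.1 * length(deg))
  thresh <- sort(as.numeric(deg), decreasing = TRUE)[k]
  expect_setequal(hubs, names(deg)[deg >= thresh])
  # all-equal degrees: everyone ties at the threshold
  ring <- cerna_network(data.frame(gene_a = sprintf("r%d", 1:4),
                                   gene_b = sprintf("r%d", c(2, 3, 4, 1))),
                        "ring")
  expect_setequal(identify_hubs(ring), ring$nodes)
  # star graph: the center always qualifies
  star <- net_from(rep("CENTER", 99), sprintf("leaf%02d", 1:99))
  expect_true("CENTER" %in% identify_hubs(star))
})

test_that("hub taxonomy separates conserved, rewired and single-network hubs", {
  leaf <- function(stem, n) sprintf("%s%02d", stem, seq_len(n))
  netA <- cerna_network(data.frame(
    gene_a = c(rep("H1", 6), rep("H2", 6)),
    gene_b = c(leaf("a", 6), leaf("b", 6))), "A")
  netB <- cerna_network(data.frame(
    gene_a = c(rep("H1", 6), rep("H2", 6)),
    gene_b = c(leaf("a", 6), leaf("c", 6))), "B")
  netC <- cerna_network(data.frame(
    gene_a = rep("H3", 4), gene_b = leaf("d", 4)), "C")
  rec <- classify_hubs(list(A = netA, B = netB, C = netC))
  expect_equal(sort(rec$gene), c("H1", "H2", "H3"))
  expect_equal(rec$category[rec$gene == "H1"], "common")
  expect_equal(rec$category[rec$gene == "H2"], "differential")
  expect_equal(rec$category[rec$gene == "H3"], "specific")
  expect_equal(rec$max_simpson[rec$gene == "H1"], 1)
  expect_equal(rec$max_simpson[rec$gene == "H2"], 0)
})

test_that("hub categories partition the hub universe on synthetic studies", {
  st <- small_study(seed = 37)
  cand <- candidate_pairs(st$interactions)
  nets <- lapply(st$profiles, build_profile_network, candidates = cand)
  diseases <- vapply(st$profiles, `[[`, character(1), "disease")
  dnets <- merge_by_disease(nets, diseases)
  rec <- classify_hubs(dnets)
  all_hubs <- unique(unlist(lapply(dnets, identify_hubs)))
  expect_equal(nrow(rec), length(all_hubs))
  expect_equal(anyDuplicated(rec$gene), 0L)
  expect_true(all(rec$category %in% c("common", "differential", "specific")))
  expect_true(all(rec$n_networks[rec$category == "specific"] == 1L))
  expect_true(all(rec$n_networks[rec$category != "specific"] > 1L))
  expect_true(all(rec$max_simpson[rec$category == "common"] > 0.8))
})
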