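# Rooting, species-overlap classification, constraints, and dating.

test_that("classify_species_overlap handles the canonical small cases", {
  sp <- ape::read.tree(text = "((A:50,B:50)S1:50,(C:60,D:60)S2:40)R;")
  # ((A1,B1),(A2,B2)): root D, both children S
  g1 <- ape::read.tree(text = "((A_1:30,B_1:30)n1:30,(A_2:40,B_2:40)n2:20)r;")
  cls1 <- classify_species_overlap(g1, c(A_1 = "A", B_1 = "B", A_2 = "A",
                                         B_2 = "B"), sp)
  expect_equal(unname(cls1$events[c("r", "n1", "n2")]), c("D", "S", "S"))
  # ((A1,A2),B1): inner D, root S
  g2 <- ape::read.tree(text = "((A_1:10,A_2:10)n1:20,B_1:30)r;")
  cls2 <- classify_species_overlap(g2, c(A_1 = "A", A_2 = "A", B_1 = "B"),
                                   sp)
  expect_equal(unname(cls2$events[c("r", "n1")]), c("S", "D"))
  # single-species family: all internal nodes D
  g3 <- ape::read.tree(text = "((A_1:10,A_2:10)n1:20,A_3:30)r;")
  cls3 <- classify_species_overlap(g3, c(A_1 = "A", A_2 = "A", A_3 = "A"),
                                   sp)
  expect_true(all(cls3$events == "D"))
  # S nodes map to the species-tree MRCA
  expect_equal(unname(cls1$species_node[["n1"]]), "S1")
  expect_equal(unname(cls1$species_age[["n1"]]), 50)
})

test_that("species-overlap duplications are always LCA-mapping
          duplications, and the two agree on loss-free families", {
  set.seed(61)
  sp <- sim_species_tree(5, 100, seed = 62)
  lca_dup <- function(gt, tipsp, v) {
    under <- exprevo:::tips_under(gt)
    map_of <- function(u) {
      spp <- unique(tipsp[gt$tip.label[under[[u]]]])
      if (length(spp) == 1) match(spp, sp$tip.label) else
        ape::getMRCA(sp, spp)
    }
    any(vapply(exprevo:::children_of(gt)[[v]],
               function(c) map_of(c) == map_of(v), TRUE))
  }
  # on arbitrary (discordant) trees, overlap-D implies LCA-D; the converse
  # can fail when a node's children span disjoint but interleaved clades
  for (rep in 1:60) {
    gt <- exprevo:::ensure_node_labels(ape::rtree(8))
    tipsp <- stats::setNames(sample(sp$tip.label, 8, TRUE), gt$tip.label)
    cls <- classify_species_overlap(gt, tipsp, sp)
    for (v in 9:(8 + gt$Nnode)) {
      lab <- exprevo:::node_label(gt, v)
      if (cls$events[[lab]] == "D") {
        expect_true(lca_dup(gt, tipsp, v))
      }
    }
  }
  # on loss-free simulated families the classifications coincide exactly
  spec <- species_tree_spec(sp)
  n_nodes <- 0L
  for (rep in 1:25) {
    fam <- simulate_gene_family(spec, family_sim_params(
      dup_rate = 2e-3, loss_rate = 0, seed = 900 + rep))
    if (fam$extinct || fam$n_tips < 3) next
    cls <- classify_species_overlap(fam$tree, fam$tip_species, sp)
    for (lab in names(cls$events)) {
      v <- exprevo:::node_index(fam$tree, lab)
      expect_equal(cls$events[[lab]] == "D",
                   lca_dup(fam$tree, fam$tip_species, v))
      n_nodes <- n_nodes + 1L
    }
  }
  expect_gt(n_nodes, 50)
})

test_that("root_tree: congruent gene tree has a zero-score DL-minimal root
          and DL scores match the brute-force oracle on every rooting", {
  sp <- ape::read.tree(text =
    "(((A:20,B:20)S1:20,C:40)S2:30,(D:50,E:50)S3:20)R;")
  # congruent gene tree
  g <- ape::read.tree(text =
    "(((a:20,b:20):20,c:40):30,(d:50,e:50):20);")
  tipsp <- c(a = "A", b = "B", c = "C", d = "D", e = "E")
  rt <- root_tree(g, sp, tipsp)
  expect_true(any(rt$candidates$dl_score[rt$candidates$is_dl_min] == 0))
  expect_equal(min(rt$candidates$dl_score), 0)
  # tree with one duplication: every candidate rooting's DL counts match
  # the independent reconciliation oracle
  g2 <- ape::read.tree(text =
    "((a1:10,(b1:6,a2:6):4):20,(c1:15,d1:15):15);")
  tipsp2 <- c(a1 = "A", b1 = "B", a2 = "A", c1 = "C", d1 = "D")
  rt2 <- root_tree(g2, sp, tipsp2)
  u2 <- ape::unroot(g2)
  for (k in seq_len(nrow(rt2$candidates))) {
    rooted <- exprevo:::root_at_edge(u2, k)
    ora <- oracle_dl(rooted, tipsp2, sp)
    expect_equal(rt2$candidates$dups[k], ora$dups)
    expect_equal(rt2$candidates$losses[k], ora$losses)
  }
})

test_that("clock-like branch lengths put the midpoint root in the
          DL-minimal set and rooting is invariant to tip order", {
  sp <- sim_species_tree(6, 200, seed = 63)
  fam <- simulate_gene_family(species_tree_spec(sp),
                              family_sim_params(dup_rate = 1e-3,
                                                seed = 64))
  skip_if(fam$n_tips < 4)
  clock <- fam$tree  # branch lengths proportional to time
  rt <- root_tree(clock, sp, fam$tip_species)
  mid_row <- rt$candidates[rt$candidates$is_midpoint, ]
  expect_true(any(mid_row$is_dl_min))
  # invariance to re-serialization / tip rotation
  reser <- ape::read.tree(text = ape::write.tree(ape::rotate(
    exprevo:::ensure_node_labels(clock), 1 + fam$n_tips)))
  rt2 <- root_tree(reser, sp, fam$tip_species)
  expect_equal(sort(rt$candidates$dl_score), sort(rt2$candidates$dl_score))
  expect_equal(root_bip <- exprevo:::root_bipartition(rt$tree),
               exprevo:::root_bipartition(rt2$tree))
})

test_that("build_constraints fixes S ages, bounds D nodes by flanking
          speciations, and defaults the root upper bound to 1105", {
  # gene tree: root D (no ancestral S), with an S node at 90 and one at 60
  g <- ape::read.tree(text =
    "(((a1:60,b1:60)n3:30,(a2:60,b2:60)n4:30)n2:10,(a3:90,b3:90)n5:10)n1;")
  tipsp <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B", a3 = "A", b3 = "B")
  sp <- ape::read.tree(text = "(A:90,B:90)SR;")
  cls <- classify_species_overlap(g, tipsp, sp)
  expect_equal(unname(cls$events[c("n1", "n2", "n3", "n4", "n5")]),
               c("D", "D", "S", "S", "S"))
  cons <- build_constraints(g, cls)
  expect_equal(unname(cons$fixed[c("n3", "n4", "n5")]), c(90, 90, 90))
  b <- cons$bounded
  expect_equal(b$lower[b$node == "n2"], 90)
  expect_equal(b$upper[b$node == "n2"], 1105)
  expect_equal(b$lower[b$node == "n1"], 90)
  expect_equal(b$upper[b$node == "n1"], 1105)
  # D node between a 90-MY ancestor-S and a 60-MY descendant-S
  g2 <- ape::read.tree(text =
    "(((a1:60,c1:60)m3:15,(a2:60,c2:60)m4:15)m2:15,b1:90)m1;")
  sp2 <- ape::read.tree(text = "((A:60,C:60)S1:30,B:90)S0;")
  tipsp2 <- c(a1 = "A", c1 = "C", a2 = "A", c2 = "C", b1 = "B")
  cls2 <- classify_species_overlap(g2, tipsp2, sp2)
  cons2 <- build_constraints(g2, cls2)
  b2 <- cons2$bounded
  expect_equal(b2$lower[b2$node == "m2"], 60)
  expect_equal(b2$upper[b2$node == "m2"], 90)
})

test_that("date_tree: all-fixed trees return the constrained ages exactly;
          clock-like families recover truth within 2% at free nodes and
          never violate duplication bounds", {
  spec <- species_tree_spec(sim_species_tree(8, 400, seed = 65))
  n_checked <- 0L
  for (rep in 1:12) {
    fam <- simulate_gene_family(spec, family_sim_params(
      dup_rate = 1.2e-3, loss_rate = 4e-4, seed = 700 + rep,
      subst_rate_mean = 2e-3, subst_rate_sdlog = 0))
    if (fam$extinct || fam$n_tips < 4) next
    truth_ages <- exprevo:::node_ages(fam$tree)
    names(truth_ages) <- exprevo:::node_label(
      fam$tree, seq_along(truth_ages))
    cls <- classify_species_overlap(fam$tree, fam$tip_species, spec$tree)
    cons <- build_constraints(fam$tree, cls)
    dt <- date_tree(fam$subst_tree, cons)
    expect_true(is_ultrametric_tol(dt$tree, 1e-6))
    # fixed nodes exact
    for (lab in names(cons$fixed)) {
      expect_equal(unname(dt$ages[[lab]]), unname(cons$fixed[[lab]]),
                   tolerance = 1e-8)
    }
    # free duplication nodes within 2% of truth and inside bounds
    if (nrow(cons$bounded)) {
      for (i in seq_len(nrow(cons$bounded))) {
        lab <- cons$bounded$node[i]
        expect_gte(dt$ages[[lab]], cons$bounded$lower[i] - 1e-6)
        expect_lte(dt$ages[[lab]], cons$bounded$upper[i] + 1e-6)
        expect_equal(unname(dt$ages[[lab]]), unname(truth_ages[[lab]]),
                     tolerance = 0.02)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 3)
})

test_that("date_tree invokes and logs the relaxation ladder on conflicting
          bounds", {
  g <- ape::read.tree(text = "((a1:10,b1:10)n2:10,c1:20)n1;")
  cons <- structure(list(
    fixed = c(n1 = 50),
    bounded = data.frame(node = "n2", lower = 80, upper = 90),
    infeasible = data.frame(node = "n2", lower = 80, upper = 90),
    root_upper_default = 1105, species_root_age = 50),
    class = "time_constraints")
  dt <- date_tree(g, cons)
  expect_gt(length(dt$relaxation), 0)
  expect_lte(dt$ages[["n2"]], 50)
})
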