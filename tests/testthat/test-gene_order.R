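random_order <- function(n, circular = TRUE) {
  gene_order(sample(paste0("g", seq_len(n))), sample(c(-1L, 1L), n, TRUE),
             circular = circular)
}

test_that("canonicalize is idempotent and rotation-invariant", {
  o <- gene_order(c("trnP", "ND6", "trnF", "CYTB"), c(-1, -1, 1, 1))
  c1 <- canonicalize(o)
  expect_identical(canonicalize(c1), c1)
  expect_equal(c1$labels[[1]], "trnF")
  set.seed(11)
  for (rep in 1:10) {
    o <- random_order(sample(3:8, 1))
    canon <- canonicalize(o)
    for (k in seq_len(length(o) - 1L)) {
      rot <- gene_order(c(o$labels[-seq_len(k)], o$labels[seq_len(k)]),
                        c(o$strands[-seq_len(k)], o$strands[seq_len(k)]))
      expect_identical(canonicalize(rot)$labels, canon$labels)
      expect_identical(canonicalize(rot)$strands, canon$strands)
    }
  }
  lin <- gene_order(c("b", "a"), circular = FALSE)
  expect_identical(canonicalize(lin), lin)
})

test_that("orders_equivalent is an equivalence relation matching brute force", {
  set.seed(12)
  brute_equiv <- function(a, b) {
    if (length(a) != length(b)) return(FALSE)
    n <- length(a)
    any(vapply(seq_len(n) - 1L, function(k) {
      idx <- ((seq_len(n) - 1L + k) %% n) + 1L
      identical(a$labels[idx], b$labels) &&
        identical(a$strands[idx], b$strands) &&
        identical(a$pseudo[idx], b$pseudo)
    }, logical(1)))
  }
  for (rep in 1:20) {
    a <- random_order(sample(3:7, 1))
    b <- if (runif(1) < 0.5) {
      k <- sample(length(a), 1)
      idx <- ((seq_along(a$labels) - 1L + k) %% length(a)) + 1L
      gene_order(a$labels[idx], a$strands[idx])
    } else random_order(length(a))
    expect_equal(orders_equivalent(a, b), brute_equiv(a, b))
    expect_true(orders_equivalent(a, a))
    expect_equal(orders_equivalent(a, b), orders_equivalent(b, a))
  }
  # strand flip breaks equivalence
  a <- gene_order(c("x", "y", "z"), c(1, 1, 1))
  b <- gene_order(c("x", "y", "z"), c(1, -1, 1))
  expect_false(orders_equivalent(a, b))
})

test_that("gene orders extract from annotations around the circle", {
  ft <- feature_table("g", "ND1", "protein", 10, 900)
  expect_length(extract_gene_order(ft, 1000), 1L)

  # an origin-wrapping feature sorts to the same canonical order as its
  # rotated linear equivalent
  wrapped <- feature_table(rep("g", 3), c("CR", "trnF", "rrnS"),
                           c("control_region", "tRNA", "rRNA"),
                           start = c(900, 100, 300),
                           end = c(1050, 200, 800))
  linear_equiv <- feature_table(rep("g", 3), c("CR", "trnF", "rrnS"),
                                c("control_region", "tRNA", "rRNA"),
                                start = c(0, 200, 400),
                                end = c(150, 300, 900))
  expect_true(orders_equivalent(extract_gene_order(wrapped, 1000),
                                extract_gene_order(linear_equiv, 1000)))

  over <- feature_table(rep("g", 2), c("ND1", "ND2"), "protein",
                        start = c(0, 80), end = c(100, 300))
  expect_error(extract_gene_order(over, 1000), "overlap")
  touch <- feature_table(rep("g", 2), c("ND1", "ND2"), "protein",
                         start = c(0, 95), end = c(100, 300))
  expect_silent(extract_gene_order(touch, 1000))
})

test_that("the derived arrangement places CYTB before ND6", {
  # the genus-wide rearrangement: CYTB precedes ND6, unlike the typical
  # vertebrate order where ND6 comes first
  sc <- aneides_preset(seed = 5L)
  ref_labels <- sim_gene_order(sc$reference)$labels
  an_labels <- sim_gene_order(sc$aneides)$labels
  expect_true(which(ref_labels == "ND6") < which(ref_labels == "CYTB"))
  expect_true(which(an_labels == "CYTB") < which(an_labels == "ND6"))
})

test_that("depth ratios flag candidate duplicated regions", {
  tr <- depth_track("g", rep(100L, 1000))
  r <- depth_ratio(tr, c(100, 200))
  expect_equal(r$ratio, 1.0)
  expect_false(r$multi_copy)

  d <- rep(100L, 1000); d[101:200] <- 200L
  r2 <- depth_ratio(depth_track("g", d), c(100, 200))
  expect_equal(r2$ratio, 2.0)
  expect_true(r2$multi_copy)

  set.seed(21)
  for (rep in 1:10) {
    d <- sample(50:400, 500, TRUE)
    reg <- sort(sample(0:500, 2))
    if (diff(reg) < 1) next
    r3 <- depth_ratio(depth_track("g", d), reg, trim = 0)
    inside <- (reg[1] + 1):reg[2]
    expect_equal(r3$ratio, mean(d[inside]) / mean(d[-inside]))
  }
  expect_error(depth_ratio(depth_track("g", c(0L, 0L, 5L)), c(2, 3), trim = 0),
               "zero")
})
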