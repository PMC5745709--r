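test_that("the genus-level rearrangement is explained by the six-gene span", {
  anc <- gene_order(c("ND5", "ND6", "trnE", "CYTB", "trnT", "IGS", "trnP",
                      "CR", "trnF"),
                    c(1, -1, -1, 1, 1, 1, -1, 1, 1))
  der <- gene_order(c("ND5", "CYTB", "trnT", "IGS", "trnP", "ND6", "trnE",
                      "IGS", "trnP", "CR", "trnF"),
                    c(1, 1, 1, 1, -1, -1, -1, 1, -1, 1, 1),
                    pseudo = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                               FALSE, FALSE, FALSE, FALSE, FALSE))
  scs <- infer_single_drl(anc, der)
  expect_gt(length(scs), 0L)
  labs <- lapply(scs, `[[`, "span_labels")
  hit <- which(vapply(labs, function(l) {
    identical(l, c("ND6", "trnE", "CYTB", "trnT", "IGS", "trnP"))
  }, logical(1)))
  expect_length(hit, 1L)
  sc <- scs[[hit]]
  # ND6+trnE survive only in the second copy, CYTB+trnT only in the first,
  # the spacer and trnP in both (one trnP copy decayed to a pseudogene)
  expect_identical(sc$retention,
                   c("second", "second", "first", "first", "both", "both"))
  expect_false(sc$identity_consistent)
})

test_that("an unchanged order always admits identity-consistent scenarios", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(2:6, 1)
    x <- gene_order(paste0("g", seq_len(n)), sample(c(-1L, 1L), n, TRUE))
    scs <- infer_single_drl(x, x)
    expect_gt(length(scs), 0L)
    expect_true(all(vapply(scs, `[[`, logical(1), "identity_consistent")))
  }
})

test_that("transposition-like derivations match exhaustive enumeration", {
  a5 <- gene_order(LETTERS[1:5], circular = TRUE)
  d5 <- gene_order(c("A", "C", "D", "B", "E"), circular = TRUE)
  impl <- impl_drl_possets(infer_single_drl(a5, d5), 5L)
  orac <- oracle_drl_possets(a5, d5)
  expect_setequal(impl, orac)
  expect_true(posset_sig(2L, 3L, 5L) %in% impl)  # span (B,C,D)

  d5b <- gene_order(c("A", "D", "C", "B", "E"), circular = TRUE)
  expect_length(infer_single_drl(a5, d5b), 0L)

  expect_error(
    infer_single_drl(a5, gene_order(c("A", "B", "Z"), circular = TRUE)),
    "absent in ancestral")
})

test_that("every returned scenario replays forward to the derived order", {
  set.seed(32)
  for (rep in 1:25) {
    case <- random_drl_case(sample(4:7, 1))
    scs <- infer_single_drl(case$ancestral, case$derived)
    expect_gt(length(scs), 0L)
    for (sc in scs) {
      k <- sc$span_length
      in1 <- seq_len(k) %in% sc$copies$position[sc$copies$copy == 1L]
      in2 <- seq_len(k) %in% sc$copies$position[sc$copies$copy == 2L]
      ps1 <- logical(k); ps2 <- logical(k)
      c1 <- sc$copies[sc$copies$copy == 1L, ]
      c2 <- sc$copies[sc$copies$copy == 2L, ]
      ps1[c1$position] <- c1$pseudo
      ps2[c2$position] <- c2$pseudo
      replay <- drl_apply(case$ancestral, sc$span_start, k, in1, in2, ps1, ps2)
      expect_true(orders_equivalent(replay, case$derived))
    }
  }
})

test_that("inference equals the exhaustive oracle on small random cases", {
  set.seed(33)
  for (rep in 1:18) {
    n <- sample(4:7, 1)
    case <- random_drl_case(n, pseudo_prob = 0.2, repeat_prob = 0.3)
    impl <- impl_drl_possets(infer_single_drl(case$ancestral, case$derived), n)
    orac <- oracle_drl_possets(case$ancestral, case$derived)
    expect_setequal(impl, orac)
    expect_true(posset_sig(case$span_start, case$span_length, n) %in% orac ||
                  length(orac) > 0L)
  }
  # linear orders too
  set.seed(34)
  for (rep in 1:6) {
    n <- sample(4:6, 1)
    case <- random_drl_case(n, circular = FALSE)
    impl <- impl_drl_possets(infer_single_drl(case$ancestral, case$derived), n)
    orac <- oracle_drl_possets(case$ancestral, case$derived)
    expect_setequal(impl, orac)
  }
})

test_that("reported spans are containment-minimal", {
  set.seed(35)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    case <- random_drl_case(n)
    scs <- infer_single_drl(case$ancestral, case$derived)
    sets <- lapply(scs, function(sc) {
      sort(((sc$span_start - 1L + seq_len(sc$span_length) - 1L) %% n) + 1L)
    })
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i != j && length(sets[[j]]) < length(sets[[i]])) {
        expect_false(all(sets[[j]] %in% sets[[i]]))
      }
    }
  }
})

test_that("strand differences are never explained by DRL", {
  anc <- gene_order(c("A", "B", "C", "D"), c(1, 1, 1, 1))
  der <- gene_order(c("A", "B", "C", "D"), c(1, -1, 1, 1))
  expect_length(infer_single_drl(anc, der), 0L)
})
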