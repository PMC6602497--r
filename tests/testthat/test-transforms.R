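test_that("method registry holds exactly the five transforms", {
  m <- walk_methods()
  expect_length(m, 5L)
  expect_setequal(m, c("squiggle", "gates", "yau", "randic", "qi"))
})

test_that("gates walk follows the cardinal unit vectors", {
  expect_equal(as.data.frame(gates_walk(""))[, c("x", "y")],
               data.frame(x = 0, y = 0))
  at <- gates_walk("AT")
  expect_equal(at$x, c(0, 0, 0))
  expect_equal(at$y, c(0, -1, 0))

  atgc <- gates_walk("ATGC")
  expect_equal(unlist(atgc[nrow(atgc), c("x", "y")], use.names = FALSE), c(0, 0))
})

test_that("gates endpoint identity (#G - #C, #T - #A) holds on random sequences", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_seq(sample(0:200, 1))
    w <- gates_walk(s)
    expect_equal(unlist(w[nrow(w), c("x", "y")], use.names = FALSE),
                 gates_endpoint_by_counts(s))
  }
})

test_that("yau walk uses unit vectors with positive x-components", {
  expect_equal(nrow(yau_walk("")), 1L)
  at <- yau_walk("AT")
  expect_equal(unlist(at[3, c("x", "y")], use.names = FALSE), c(1, 0))

  set.seed(7)
  w <- yau_walk(random_seq(300))
  dx <- diff(w$x); dy <- diff(w$y)
  expect_true(all(abs(sqrt(dx^2 + dy^2) - 1) < 1e-12))
  expect_true(all(dx > 0))
  expect_true(all(diff(w$x) > 0)) # strictly increasing x
})

test_that("squiggle walk emits two half-steps per base", {
  expect_equal(as.data.frame(squiggle_walk("A"))[, c("x", "y")],
               data.frame(x = c(0, 0.5, 1), y = c(0, 0.5, 0)))
  expect_equal(as.data.frame(squiggle_walk("G"))[, c("x", "y")],
               data.frame(x = c(0, 0.5, 1), y = c(0, 0.5, 1)))
  expect_equal(squiggle_walk("GGGG")$y[9], 4)
})

test_that("poly-G maximizes the squiggle endpoint among all 4-mers", {
  # independent oracle: net y per base is +1 for G, -1 for C, 0 for A/T,
  # so endpoint height is #G - #C; enumerate all 256 4-mers
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4)))
  oracle_end <- vapply(strsplit(kmers, ""), function(b) {
    sum(b == "G") - sum(b == "C")
  }, numeric(1))
  impl_end <- vapply(kmers, function(k) squiggle_walk(k)$y[9], numeric(1),
                     USE.NAMES = FALSE)
  expect_equal(impl_end, oracle_end)
  expect_equal(kmers[which.max(impl_end)], "GGGG")
})

test_that("tablature walks place bases and dinucleotides at fixed levels", {
  expect_equal(as.data.frame(randic_walk("A"))[, c("x", "y")],
               data.frame(x = 0, y = 3))
  expect_equal(as.data.frame(randic_walk("AT"))[, c("x", "y")],
               data.frame(x = c(0, 1), y = c(3, 2)))
  expect_equal(nrow(randic_walk("")), 0L)

  expect_equal(as.data.frame(qi_walk("AA"))[, c("x", "y")],
               data.frame(x = 0, y = 0))
  expect_equal(as.data.frame(qi_walk("ATG"))[, c("x", "y")],
               data.frame(x = c(0, 1), y = c(3, 14)))
  expect_equal(nrow(qi_walk("A")), 0L)
  expect_equal(nrow(qi_walk("")), 0L)
})

test_that("point-count laws hold for all methods across lengths", {
  set.seed(11)
  for (len in c(0L, 1L, 2L, 3L, 17L, 100L)) {
    s <- random_seq(len)
    for (m in walk_methods()) {
      expect_equal(nrow(walk_fn(m)(s)), walk_point_count(m, len),
                   info = sprintf("method=%s len=%d", m, len))
    }
  }
})

test_that("tablature x-coordinates are exactly 0,1,2,...", {
  set.seed(3)
  s <- random_seq(50)
  expect_equal(randic_walk(s)$x, as.numeric(0:49))
  expect_equal(qi_walk(s)$x, as.numeric(0:48))
})

test_that("cumulative walks are additive under concatenation", {
  set.seed(5)
  for (m in c("gates", "yau", "squiggle")) {
    s1 <- random_seq(40); s2 <- random_seq(25)
    whole <- walk_fn(m)(paste0(s1, s2))
    w1 <- walk_fn(m)(s1)
    w2 <- walk_fn(m)(s2)
    end <- w1[nrow(w1), ]
    shifted <- data.frame(x = w2$x[-1] + end$x, y = w2$y[-1] + end$y)
    expect_equal(data.frame(x = whole$x, y = whole$y),
                 rbind(data.frame(x = w1$x, y = w1$y), shifted),
                 info = m)
  }
})

test_that("walk_transform dispatches and stamps provenance", {
  rec <- parse_fasta(">s1\nACGT\n", source_file = "f.fa")
  expect_equal(nrow(walk_transform(rec, "gates")), 5L)
  expect_equal(nrow(walk_transform(rec, "squiggle")), 9L)
  expect_equal(nrow(walk_transform(rec, "qi")), 3L)

  w <- walk_transform(rec, "yau")
  expect_equal(attr(w, "seq_id"), "s1")
  expect_equal(attr(w, "source_file"), "f.fa")
  expect_equal(attr(w, "n_bases"), 4L)

  err <- expect_error(walk_transform(rec, "zigzag"),
                      class = "dnawalkr_argument_error")
  for (m in walk_methods()) expect_match(conditionMessage(err), m)
})

test_that("glance and tidy expose walk metadata and points", {
  w <- gates_walk("ACGT", seq_id = "s1", source_file = "f.fa")
  g <- glance(w)
  expect_equal(g$n_points, 5L)
  expect_equal(g$n_bases, 4L)
  expect_equal(g$method, "gates")

  td <- tidy(w)
  expect_equal(nrow(td), 5L)
  expect_equal(unique(td$seq_id), "s1")
  expect_equal(td$idx, 0:4)
})
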