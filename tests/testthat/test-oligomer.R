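test_that("oligomer_spec validates cap pairing and orientation", {
  sp <- oligomer_spec(4, "Ace", "COO-", 1)
  expect_s3_class(sp, "pa_oligomer_spec")
  expect_error(oligomer_spec(4, "Ace", "NH3+", 1), "pair")
  expect_error(oligomer_spec(4, "NMe", "COO-", 1), "pair")
  expect_error(oligomer_spec(0, "Ace", "COO-", 1), "n_units")
  expect_error(oligomer_spec(2, "Ace", "COO-", 3), "orientation")
})

test_that("oligomer labels reflect chemistry and orientation", {
  expect_match(oligomer_label(oligomer_spec(4, "Ace", "COO-", 1)),
               "Ace-\\[6-AHA\\]4-COO-")
  lab2 <- oligomer_label(oligomer_spec(4, "Ace", "COO-", 2))
  expect_match(lab2, "OOC")
  specs <- enumerate_orientations(oligomer_spec(4, "Ace", "COO-", 1))
  expect_equal(vapply(specs, function(s) s$orientation, 0L), 1:2)
})

test_that("acetyl/carboxylate tetramer has the expected composition", {
  ol <- build_oligomer(oligomer_spec(4, "Ace", "COO-", 1))
  at <- ol$structure$atoms
  expect_equal(nrow(at), 83)
  # C6H6O(Ace) + 4 x C6H11NO(AHA core) + extra O on the carboxylate terminus
  expect_equal(sum(at$element == "C"), 26)
  expect_equal(sum(at$element == "N"), 4)
  expect_equal(sum(at$element == "O"), 6)
  expect_equal(sum(at$element == "H"), 47)
  expect_equal(sum(ol$bonds$kind == "amide"), 4)
  expect_equal(ol$formal_charge, -1)
})

test_that("amine/ammonium tetramer carries +1 and one less rotatable bond", {
  ol <- build_oligomer(oligomer_spec(4, "NMe", "NH3+", 1))
  expect_equal(ol$formal_charge, 1)
  expect_equal(nrow(ol$rotatable), 23)
  expect_equal(sum(ol$bonds$kind == "amide"), 4)
})

test_that("rotatable bonds match an independent graph scan", {
  for (sp in list(oligomer_spec(4, "Ace", "COO-", 1),
                  oligomer_spec(2, "NMe", "NH3+", 1),
                  oligomer_spec(1, "Ace", "COO-", 1))) {
    ol <- build_oligomer(sp)
    got <- sort(paste(ol$rotatable$i, ol$rotatable$j))
    want_rows <- oracle_rotatable(ol)
    want <- sort(paste(ol$bonds$i[want_rows], ol$bonds$j[want_rows]))
    expect_equal(got, want)
  }
  expect_equal(nrow(build_oligomer(oligomer_spec(4, "Ace", "COO-", 1))$rotatable),
               24)
})

test_that("amide dihedrals are frozen trans and bond lengths are physical", {
  ol <- build_oligomer(oligomer_spec(3, "Ace", "COO-", 1))
  m <- coords(ol$structure)
  at <- ol$structure$atoms
  amides <- ol$bonds[ol$bonds$kind == "amide", ]
  for (r in seq_len(nrow(amides))) {
    ci <- amides$i[r]; ni <- amides$j[r]
    if (at$element[ci] != "C") { tmp <- ci; ci <- ni; ni <- tmp }
    # omega measured O=C-N-H (trans amide: O and H anti-planar -> 0; the
    # backbone definition C(alpha)-C-N-C(alpha) is 180)
    o <- which(at$element == "O" &
                 sqrt(rowSums(sweep(m, 2, m[ci, ])^2)) < 1.4)[1]
    nb_n <- setdiff(c(ol$bonds$i[ol$bonds$j == ni], ol$bonds$j[ol$bonds$i == ni]),
                    ci)
    ca2 <- nb_n[at$element[nb_n] == "C"][1]
    ca1 <- setdiff(c(ol$bonds$i[ol$bonds$j == ci], ol$bonds$j[ol$bonds$i == ci]),
                   c(ni, o))
    ca1 <- ca1[at$element[ca1] == "C"][1]
    omega <- dihedral_angle(m[ca1, ], m[ci, ], m[ni, ], m[ca2, ])
    expect_equal(abs(omega), 180, tolerance = 1e-6)
    expect_equal(sqrt(sum((m[ci, ] - m[ni, ])^2)), 1.33, tolerance = 1e-6)
  }
  blen <- sqrt(rowSums((m[ol$bonds$i, ] - m[ol$bonds$j, ])^2))
  expect_true(all(blen > 0.9 & blen < 1.65))
})

test_that("dihedral overrides are realised in the geometry", {
  sp <- oligomer_spec(2, "Ace", "COO-", 1)
  ol <- build_oligomer(sp)
  dh <- ol$dihedrals
  row <- 3
  dh[row] <- 63
  ol2 <- build_oligomer(sp, dihedrals = dh)
  m <- coords(ol2$structure)
  rb <- ol2$rotatable[row, ]
  expect_equal(dihedral_angle(m[rb$a, ], m[rb$i, ], m[rb$j, ], m[rb$d, ]),
               63, tolerance = 1e-6)
})

test_that("internal clash detection agrees with a brute-force rule", {
  sp <- oligomer_spec(3, "Ace", "COO-", 1)
  ol0 <- build_oligomer(sp)
  set.seed(5)
  for (trial in 1:6) {
    dh <- sample(c(-60, 0, 60, 180), nrow(ol0$rotatable), replace = TRUE)
    ol <- build_oligomer(sp, dihedrals = dh)
    hv <- which(ol$structure$atoms$element != "H")
    m <- coords(ol$structure)
    # independent >= 3-bond separation via BFS depth 2
    adj <- lapply(seq_len(nrow(m)), function(i)
      c(ol$bonds$j[ol$bonds$i == i], ol$bonds$i[ol$bonds$j == i]))
    near <- function(i) unique(c(i, unlist(adj[i]), unlist(adj[unlist(adj[i])])))
    clash <- FALSE
    for (ii in seq_along(hv)) {
      for (jj in seq_len(ii - 1L)) {
        a <- hv[ii]; b <- hv[jj]
        if (b %in% near(a)) next
        if (sqrt(sum((m[a, ] - m[b, ])^2)) < 2.0) clash <- TRUE
      }
    }
    expect_equal(has_internal_clash(ol, 2.0), clash)
  }
})

test_that("the attack amide sits between the two central units", {
  ol <- build_oligomer(oligomer_spec(4, "Ace", "COO-", 1))
  at <- ol$structure$atoms
  units <- sort(ol$unit_of[unlist(ol$attack_amide)])
  expect_true(all(units %in% 2:3))
  ol2 <- build_oligomer(oligomer_spec(2, "Ace", "COO-", 1))
  units2 <- sort(ol2$unit_of[unlist(ol2$attack_amide)])
  expect_true(all(units2 %in% 1:2))
})

test_that("monomer builds degenerate correctly", {
  ol <- build_oligomer(oligomer_spec(1, "NMe", "NH3+", 1))
  expect_equal(nrow(ol$structure$atoms), 27)
  expect_false(has_internal_clash(ol))
})
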