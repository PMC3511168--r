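ev_catalog <- function() {
  family_catalog(data.frame(
    family_id = c("f1", "f2", "f3", "u3", "h1", "c1", "c2"),
    clan_id = c("", "", "", "", "", "CL1", "CL1"),
    class = c("CD", "CD", "CD", "CD", "HACA", "CD", "CD"),
    fun = c(rep("modification_guide", 3), "cleavage_only",
            rep("modification_guide", 3))))
}

test_that("total evidence intersects the three sets with exclusions applied", {
  cat <- ev_catalog()
  r <- total_evidence(A = c("f1", "f2"), B = c("f1", "f2"), C = c("f1", "f2"),
                      catalog = cat)
  expect_equal(r$intersection, c("f1", "f2"))
  expect_equal(unname(r$sizes["ABC"]), 2L)
  d <- total_evidence(A = "f1", B = "f2", C = "f3", catalog = cat)
  expect_equal(length(d$intersection), 0L)
  expect_equal(unname(d$sizes[c("AB", "AC", "BC")]), c(0L, 0L, 0L))
  # H/ACA and cleavage-only families are excluded, not intersected
  e <- total_evidence(A = c("f1", "u3", "h1"), B = c("f1", "u3"),
                      C = c("f1", "h1"), catalog = cat)
  expect_equal(e$intersection, "f1")
  expect_setequal(e$exclusions$family_id, c("u3", "h1"))
  expect_setequal(e$exclusions$reason, c("cleavage_only", "non_CD_class"))
  expect_true(all(r$sizes["ABC"] <= r$sizes[c("A", "B", "C")]))
  expect_error(total_evidence("zzz", "f1", "f1", cat), "unknown family")
})

test_that("clan expansion verdicts distinguish shared from distinct targets", {
  cat <- ev_catalog()
  shared <- clan_expansion_check("CL1", c("c1", "c2"),
                                 list(c1 = "SSU_c0100", c2 = "SSU_c0100"), cat)
  expect_equal(shared$verdict, "artefactual_split_or_orthologous")
  distinct <- clan_expansion_check("CL1", c("c1", "c2"),
                                   list(c1 = "SSU_c0100", c2 = "SSU_c0140"), cat)
  expect_equal(distinct$verdict, "duplication")
  na <- clan_expansion_check("CL1", c("c1"), list(), cat)
  expect_equal(na$verdict, "not_applicable")
})

test_that("evidence cardinalities on the synthetic fixture are self-consistent", {
  rep_ <- get_small_report()
  s <- unlist(rep_$evidence$sizes)
  expect_lte(s["ABC"], min(s["A"], s["B"], s["C"]))
  expect_lte(s["AB"], min(s["A"], s["B"]))
  expect_lte(s["ABC"], min(s["AB"], s["AC"], s["BC"]))
  # every intersected family is a C/D modification guide by construction
  b <- get_small_bundle()
  fams <- b$families
  inter <- rep_$evidence$intersection
  expect_true(all(fams$class[fams$family_id %in% inter] == "CD"))
  expect_true(all(fams$fun[fams$family_id %in% inter] == "modification_guide"))
})
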