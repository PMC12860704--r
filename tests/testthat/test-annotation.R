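test_that("shorthand grammar parses class, chains, ether and sn tags", {
  ann <- parse_lipids(c("FFA(16:0)", "PE(P-18:0/20:4)", "TAG52:2-FA18:1",
                        "CE 18:2", "pe(o-34:2)", " SM( 36:1 ) "))
  expect_equal(ann$class_code,
               c("FFA", "PE-P", "TAG", "CE", "PE-O", "SM"))
  expect_equal(ann$total_carbons, c(16L, 38L, 52L, 18L, 34L, 36L))
  expect_equal(ann$total_double_bonds, c(0L, 4L, 2L, 2L, 2L, 1L))
  expect_equal(ann$ether_type, c("none", "P", "none", "none", "O", "none"))
  expect_equal(ann$sn_fatty_acid,
               c(NA, NA, "FA18:1", NA, NA, NA))
})

test_that("malformed and out-of-registry names are rejected", {
  expect_error(parse_lipids("FFA(16)"), "malformed|cannot parse")
  expect_error(parse_lipids("XYZ(16:0)"), "unknown lipid class")
  expect_error(parse_lipids("PC(O-34:2)"), "ether prefix")
  expect_error(parse_lipids("FFA(4:9)"), "double bonds exceed")
  expect_error(parse_lipids(""), "non-empty")
})

test_that("parse -> render -> parse is the identity on the grammar", {
  panel <- lipidflow:::.build_panel(c(FFA = 16, TAG = 40, `PE-P` = 10,
                                      PC = 20, AC = 12, CER = 6))
  rendered <- render_lipid_name(panel)
  again <- parse_lipids(rendered)
  expect_equal(again$class_code, panel$class_code)
  expect_equal(again$total_carbons, panel$total_carbons)
  expect_equal(again$total_double_bonds, panel$total_double_bonds)
  expect_equal(again$ether_type, panel$ether_type)
  expect_equal(again$sn_fatty_acid, panel$sn_fatty_acid)
})

test_that("saturation categories follow the double-bond convention", {
  expect_equal(as.character(classify_saturation(c(0, 1, 2, 6))),
               c("saturated", "monounsaturated", "polyunsaturated",
                 "polyunsaturated"))
})

test_that("acylcarnitine chain windows are C5-C14 and C16-C20", {
  expect_equal(classify_chain_length(c(8, 14, 5), "acylcarnitine"),
               rep("intermediate", 3))
  expect_equal(classify_chain_length(c(16, 18, 20), "acylcarnitine"),
               rep("long", 3))
  expect_equal(classify_chain_length(c(2, 4, 15, 22), "acylcarnitine"),
               rep("excluded", 4))
  expect_equal(classify_chain_length(c(14, 16, 24, 26), "ffa"),
               c("short", "long", "long", "short"))
})

test_that("TAG collapse sums isotopomers and conserves class totals", {
  m <- rbind(c(1, 10), c(2, 20), c(3, 30), c(5, 50))
  rownames(m) <- c("TAG52:2-FA16:0", "TAG52:2-FA18:1", "TAG52:2-FA18:2",
                   "FFA(16:0)")
  out <- collapse_tag_isotopomers(wide_tbl(m))
  expect_equal(out$feature, c("TAG52:2", "FFA(16:0)"))
  expect_equal(unlist(out[out$feature == "TAG52:2", -1], use.names = FALSE),
               c(6, 60))
  map <- attr(out, "tag_mapping")
  expect_equal(sort(map$member[map$collapsed == "TAG52:2"]),
               sort(rownames(m)[1:3]))

  # no-TAG input passes through untouched
  no_tag <- wide_tbl(m[4, , drop = FALSE])
  expect_equal(collapse_tag_isotopomers(no_tag), no_tag,
               ignore_attr = TRUE)
})

test_that("collapse conserves per-sample TAG sums on the generated panel", {
  set.seed(42)
  panel <- lipidflow:::.build_panel(c(TAG = 445, PC = 10))
  m <- matrix(rexp(nrow(panel) * 6), nrow(panel), 6,
              dimnames = list(panel$feature, paste0("s", 1:6)))
  out <- collapse_tag_isotopomers(wide_tbl(m), panel)
  tag_rows <- startsWith(out$feature, "TAG")
  expect_equal(sum(tag_rows), 95)  # 445 isotopomers over 95 compositions
  expect_equal(colSums(as.matrix(out[tag_rows, -1])),
               colSums(m[startsWith(rownames(m), "TAG"), ]))
  # features partition into classes: disjoint cover
  ann <- parse_lipids(out$feature)
  expect_true(all(table(ann$feature) == 1))
  expect_true(all(ann$class_code %in% lipid_classes()))
})

test_that("untagged TAG colliding with a collapsed group is an error", {
  m <- matrix(1, 3, 2)
  rownames(m) <- c("TAG52:2-FA16:0", "TAG52:2-FA18:1", "TAG52:2")
  expect_error(collapse_tag_isotopomers(wide_tbl(m)), "collides")
})
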