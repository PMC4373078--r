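test_that("canonical character set matches the published scoring system", {
  def <- canonical_character_set()
  expect_equal(def$code,
               c("IN", "TI", "HE", "DO", "SP", "SO", "HO", "SH", "SC",
                 "CO", "RO", "GR", "CD", "RI", "RD"))
  expect_true(all(lengths(def$states) %in% 2:5))
  expect_true(all(def$min_state >= 0 & def$max_state <= 5))
  # rib depth only applicable when ribs are present
  rd <- def[def$code == "RD", ]
  expect_equal(rd$na_code, "RI")
  expect_equal(rd$na_states[[1]], 0L)
  # patterning traits only applicable when patterning is present
  for (code in c("SP", "SO", "HO")) {
    expect_equal(def$na_code[def$code == code], "DO")
  }
  expect_equal(def$na_code[def$code == "SC"], "SH")
})

test_that("score tables parse, normalize and validate", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "specimen_id,population_code,group,IN,TI,HE,DO,SP,SO,HO,SH,SC,CO,RO,GR,CD,RI,RD",
    "a,P1,native,2,1,0,2,\"2, 3\",2,1,2,2,1,2,2,0,3,1",
    "b,P1,native,3,1,0,0,na,na,na,1,na,1,2,2,0,0,na"), tmp)
  cm <- read_character_table(tmp)
  expect_s3_class(cm, "character_matrix")
  expect_equal(cm$SP, c("2,3", NA))       # borderline cell normalized
  expect_equal(cm$RD[2], NA_character_)   # na accepted where RI = 0
  expect_equal(nrow(cm), 2)
})

test_that("validation reports offending cells with coordinates", {
  base <- tibble::tibble(specimen_id = "a", population_code = "P",
                         group = "native", IN = "2", TI = "1", HE = "0",
                         DO = "2", SP = "1", SO = "2", HO = "1", SH = "2",
                         SC = "2", CO = "1", RO = "2", GR = "2", CD = "0",
                         RI = "3", RD = "1")
  # state outside the allowed range, naming specimen and character
  bad <- base; bad$IN <- "7"
  expect_error(as_character_matrix(bad), "outside allowed range.*'a'.*IN")
  # na where the trait is applicable
  bad <- base; bad$SC <- "na"
  expect_error(as_character_matrix(bad), "'na' not permitted")
  # unknown character column
  bad <- base; bad$XX <- "1"
  expect_error(as_character_matrix(bad), "unknown character")
  # duplicate specimen ids
  bad <- dplyr::bind_rows(base, base)
  expect_error(as_character_matrix(bad), "duplicate specimen_id")
})

test_that("unbleached rows may carry na in otherwise applicable traits", {
  base <- tibble::tibble(specimen_id = "u", population_code = "P",
                         group = "invasive", unbleached = TRUE,
                         IN = "4", TI = "5", HE = "0", DO = "0", SP = "na",
                         SO = "na", HO = "na", SH = "1", SC = "na",
                         CO = "1", RO = "2", GR = "2", CD = "0", RI = "3",
                         RD = "na")  # RD na despite RI = 3: allowed, unbleached
  expect_s3_class(as_character_matrix(base), "character_matrix")
  base$unbleached <- FALSE
  expect_error(as_character_matrix(base), "'na' not permitted")
})

test_that("multistate collapse takes arithmetic means and is idempotent", {
  scores <- melanoides_shell_scores()
  num <- collapse_multistate(scores)
  # borderline cells collapse to the midpoint
  expect_equal(num$IN[num$specimen_id == "CD05-06 F1"], 2.5)
  expect_equal(num$SO[num$specimen_id == "CD06-A"], 1.5)
  expect_equal(num$RD[num$specimen_id == "CD10/1-4"], 1.5)
  # single states map to themselves
  expect_equal(num$IN[num$specimen_id == "CD01/1"], 4)
  # inapplicable cells stay missing
  expect_true(is.na(num$SP[num$specimen_id == "CD01/1"]))
  # every value within the character's theoretical range
  def <- canonical_character_set()
  for (i in seq_len(nrow(def))) {
    v <- num[[def$code[i]]]
    expect_true(all(is.na(v) | (v >= def$min_state[i] & v <= def$max_state[i])))
  }
  # commutes with row reordering
  shuf <- scores[rev(seq_len(nrow(scores))), ]
  attr(shuf, "definitions") <- character_definitions(scores)
  class(shuf) <- class(scores)
  num2 <- collapse_multistate(shuf)
  expect_equal(num2[rev(seq_len(nrow(num2))), ], num, ignore_attr = TRUE)
})

test_that("the bundled shell-score table is complete", {
  scores <- melanoides_shell_scores()
  expect_equal(nrow(scores), 49)
  expect_equal(sum(scores$unbleached), 3)
  expect_setequal(unique(scores$group), c("native", "invasive"))
  expect_equal(sum(scores$species == "Melanoides tuberculata"), 38)
})
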