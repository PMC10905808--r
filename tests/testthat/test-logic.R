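# internal AST constructors, used to state expected parses literally
af <- asNamespace("redcapqc")

test_that("tokenizer classifies references and reproduces the source", {
  toks <- tokenize_logic("[age] > 18")
  expect_identical(vapply(toks, `[[`, character(1), "kind"),
                   c("field_ref", "operator", "number"))
  toks <- tokenize_logic("[comorb(2)] = '1'")
  expect_identical(toks[[1]]$kind, "checkbox_ref")
  expect_identical(toks[[1]]$value, list(name = "comorb", code = "2"))
  expect_identical(toks[[3]]$kind, "string")
  toks <- tokenize_logic("[event-name] = 'baseline_arm_1'")
  expect_identical(toks[[1]]$kind, "smart_var")

  # concatenating token texts at their recorded offsets reproduces the source
  for (src in c("[age] >= 18 and [sex] = '1'", "2+3 * datediff([a],[b],'y')",
                "not([x]<>'') or [y(1)]=1")) {
    toks <- tokenize_logic(src)
    rebuilt <- strrep(" ", nchar(src))
    for (t in toks) {
      substr(rebuilt, t$pos + 1L, t$pos + nchar(t$text)) <- t$text
    }
    expect_identical(gsub(" ", "", rebuilt), gsub(" ", "", src))
    for (t in toks) {
      expect_identical(substr(src, t$pos + 1L, t$pos + nchar(t$text)), t$text)
    }
  }

  expect_error(tokenize_logic("[age"), class = "rcqc_parse_error")
  expect_error(tokenize_logic("[a] = 'oops"), class = "rcqc_parse_error")
})

test_that("parser applies the documented precedence table", {
  # or < and: hand-derived AST
  expect_identical(
    parse_logic("[a] = 1 or [b] = 2 and [c] = 3"),
    af$ast_binary("or",
      af$ast_binary("=", af$ast_field("a"), af$ast_lit("number", 1)),
      af$ast_binary("and",
        af$ast_binary("=", af$ast_field("b"), af$ast_lit("number", 2)),
        af$ast_binary("=", af$ast_field("c"), af$ast_lit("number", 3)))))
  # parentheses override
  expect_identical(
    parse_logic("([a] = 1 or [b] = 2) and [c] = 3"),
    af$ast_binary("and",
      af$ast_binary("or",
        af$ast_binary("=", af$ast_field("a"), af$ast_lit("number", 1)),
        af$ast_binary("=", af$ast_field("b"), af$ast_lit("number", 2))),
      af$ast_binary("=", af$ast_field("c"), af$ast_lit("number", 3))))
  # multiplicative over additive; power right-associative; -x^2 = -(x^2)
  expect_identical(parse_logic("1 + 2 * 3"),
                   af$ast_binary("+", af$ast_lit("number", 1),
                                 af$ast_binary("*", af$ast_lit("number", 2),
                                               af$ast_lit("number", 3))))
  expect_identical(parse_logic("-[x] ^ 2"),
                   af$ast_unary("neg",
                                af$ast_binary("^", af$ast_field("x"),
                                              af$ast_lit("number", 2))))
  expect_identical(parse_logic("2 ^ 3 ^ 2"),
                   af$ast_binary("^", af$ast_lit("number", 2),
                                 af$ast_binary("^", af$ast_lit("number", 3),
                                               af$ast_lit("number", 2))))
  # not binds between and and the comparisons
  expect_identical(parse_logic("not [a] = 1 and [b] = 2"),
                   af$ast_binary("and",
                     af$ast_unary("not",
                       af$ast_binary("=", af$ast_field("a"),
                                     af$ast_lit("number", 1))),
                     af$ast_binary("=", af$ast_field("b"),
                                   af$ast_lit("number", 2))))
  expect_identical(parse_logic("datediff([dob],[visit],'y')"),
                   af$ast_call("datediff",
                               list(af$ast_field("dob"), af$ast_field("visit"),
                                    af$ast_lit("string", "y"))))
})

test_that("parser rejects malformed input with positions", {
  expect_error(parse_logic("[a] ="), class = "rcqc_parse_error")
  expect_error(parse_logic("[a] = 1 or"), class = "rcqc_parse_error")
  expect_error(parse_logic("foo([a])"), "unknown function",
               class = "rcqc_parse_error")
  expect_error(parse_logic("abs([a],[b])"), class = "rcqc_parse_error")
  expect_error(parse_logic("[a] = 1 = 2"), "non-associative",
               class = "rcqc_parse_error")
  err <- tryCatch(parse_logic("[a] @ 1"), rcqc_parse_error = function(e) e)
  expect_identical(err$position, 4L)
})

test_that("evaluation follows blank and Kleene semantics", {
  expect_equal(eval_logic("2 + 3 * 4"), 14)
  ctx <- eval_context(row = list(copd = "", a = "5", b = "1"))
  expect_true(eval_logic("[copd] = ''", ctx))
  expect_false(eval_logic("[copd] <> ''", ctx))
  expect_true(eval_logic("[a] <> ''", ctx))
  expect_equal(eval_logic("if([a] > 2, 10, 20)", ctx), 10)
  expect_true(eval_logic("[copd] > 2 or [b] = 1", ctx))   # or(NA, TRUE)
  expect_identical(eval_logic("[copd] > 2 and [b] = 1", ctx), NA)
  expect_identical(eval_logic("[copd] + 1", ctx), NA)     # blank arithmetic
  expect_identical(eval_logic("[copd] = '1'", ctx), NA)   # blank comparison
  # numeric-vs-string comparison: numeric when both sides parse
  expect_true(eval_logic("[a] = '5.0'", ctx))
  expect_false(eval_logic("[a] = 'x5'", ctx))
  # checkbox truthiness: bare reference means = '1'
  ctx2 <- eval_context(row = list(comorb___2 = "1", comorb___3 = "0"))
  expect_true(eval_logic("[comorb(2)] and not [comorb(3)]", ctx2))
})

test_that("functions and failure modes behave as documented", {
  ctx <- eval_context()
  expect_equal(eval_logic("round(2.5)"), 3)          # half away from zero
  expect_equal(eval_logic("round(-2.5)"), -3)
  expect_equal(eval_logic("round(2.345, 2)"), 2.35)
  expect_equal(eval_logic("roundup(2.01)"), 3)
  expect_equal(eval_logic("rounddown(2.99)"), 2)
  expect_equal(eval_logic("min(3, 1, 2)"), 1)
  expect_equal(eval_logic("mean(2, 4)"), 3)
  ctxb <- eval_context(row = list(x = ""))
  expect_equal(eval_logic("sum([x], 2, 3)", ctxb), 5)  # blanks ignored
  expect_identical(eval_logic("min([x])", ctxb), NA)
  expect_equal(eval_logic("abs(0 - 4) + sqrt(9)"), 7)

  # division by zero: blank plus a note, never a crash
  ctx3 <- eval_context()
  expect_identical(eval_logic("1 / 0", ctx3), NA)
  expect_match(eval_notes(ctx3), "division by zero")

  # datediff: REDCap approximations, unsigned by default
  expect_equal(eval_logic("datediff('2000-01-01','2020-01-01','d')"), 7305)
  expect_equal(eval_logic("datediff('2000-01-01','2020-01-01','y')"),
               7305 / 365.2425)
  expect_equal(eval_logic("datediff('2020-01-01','2000-01-01','y')"),
               7305 / 365.2425)  # absolute
  expect_equal(eval_logic("datediff('2020-01-01','2000-01-01','y', 'true')"),
               -7305 / 365.2425) # signed
  ctx4 <- eval_context()
  expect_identical(eval_logic("datediff('not a date','2020-01-01','y')", ctx4),
                   NA)
  expect_match(eval_notes(ctx4), "datediff")
})

test_that("property: datediff of a date with itself is zero in every unit", {
  withr::with_seed(42, {
    dates <- format(as.Date("1950-01-01") + sample(0:25000, 20))
    for (d in dates) {
      for (u in c("y", "M", "d", "h", "m", "s")) {
        expect_equal(eval_logic(sprintf("datediff('%s','%s','%s')", d, d, u)),
                     0)
      }
    }
  })
})

test_that("property: evaluator agrees with the brute-force Kleene oracle", {
  withr::with_seed(101, {
    for (rep in seq_len(300)) {
      src <- rand_bool_expr(depth = 3)
      vals <- rand_context_values()
      ast <- parse_logic(src)
      got <- eval_logic(src, eval_context(row = vals))
      want <- oracle_truth(ast, vals)
      expect_identical(as.logical(got), as.logical(want), label = src)
    }
  })
})

test_that("property: parse(render_logic(ast)) round-trips every AST", {
  withr::with_seed(77, {
    for (rep in seq_len(200)) {
      ast0 <- if (rep %% 2 == 0) parse_logic(rand_bool_expr(3))
              else rand_value_ast(3)
      expect_identical(parse_logic(render_logic(ast0)), ast0)
    }
  })
})

test_that("property: concretizing a blank never falsifies a true disjunction", {
  # and-free, not-free disjunctions of comparisons against non-blank
  # literals: a disjunct touching a blank field is missing, never true,
  # so the true disjunct survives any replacement.
  withr::with_seed(13, {
    for (rep in seq_len(200)) {
      n_terms <- sample(2:4, 1)
      src <- paste(replicate(n_terms, rand_cmp_string(allow_blank_lit = FALSE)),
                   collapse = " or ")
      vals <- rand_context_values()
      if (!isTRUE(eval_logic(src, eval_context(row = vals)))) next
      blanks <- names(vals)[vapply(vals, identical, logical(1), "")]
      for (f in blanks) {
        for (v in c("0", "1", "2")) {
          vals2 <- vals
          vals2[[f]] <- v
          expect_false(identical(eval_logic(src, eval_context(row = vals2)),
                                 FALSE), label = src)
        }
      }
    }
  })
})
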