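test_that("the worked-example table has the fuzzy structure of the model", {
  tab <- run_error_table()
  expect_equal(nrow(tab), 6 * 4)

  # core rows: value and error identically zero
  core <- tab[tab$r == 1, ]
  expect_identical(core$numerical, rep(0, 4))
  expect_identical(core$abs_error, rep(0, 4))

  # upper branch is the exact negative of the lower branch, row by row
  lo <- tab[tab$beta == 0, ]
  up <- tab[tab$beta == 1, ]
  expect_identical(up$numerical[order(up$r)], -lo$numerical[order(lo$r)])

  # lower branch is negative and shrinks in magnitude toward the core
  expect_true(all(lo$numerical[order(lo$r)][1:5] < 0))
  expect_true(all(diff(abs(lo$numerical[order(lo$r)])) < 0))
})

test_that("table CSV output round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- run_error_table(out = path)
  back <- utils::read.csv(path)
  expect_equal(as.data.frame(tab), back, tolerance = 1e-12)
})

test_that("solution CSV round-trips the grid exactly", {
  cfg <- preset_worked_example()
  sol <- solve_crisp(at_sample(cfg$model, 0, 1), cfg$grid)
  td <- tidy(sol)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(td, path, row.names = FALSE)
  back <- utils::read.csv(path)
  rebuilt <- matrix(back$u[order(back$n, back$i)],
                    nrow = cfg$grid$N + 1, byrow = TRUE)
  expect_equal(rebuilt, unname(sol$u), tolerance = 1e-12)
})

test_that("accuracy improves as the fractional order approaches one", {
  res <- suppressWarnings(sweep_alpha(alphas = c(0.5, 0.7, 0.9)))
  expect_true(all(diff(res$abs_error) < 0))
  expect_error(sweep_alpha(alphas = c(0.5, 1.2)), "0, 1")
})

test_that("the alpha = 1 sweep entry is exactly a classical FTCS run", {
  cfg <- preset_worked_example(alpha = 1)
  res <- sweep_alpha(cfg, alphas = 1)
  g <- cfg$grid
  ref <- ftcs_reference(
    exp(-x_nodes(g)), g$dx, g$dt, g$N,
    k_fn = function(x, t) rep(t^2, length(x)),
    bc_left = function(t) exact_crisp(0, t, cfg$spec),
    bc_right = function(t) exact_crisp(g$L, t, cfg$spec))
  i4 <- which(x_nodes(g) == 4)
  expect_equal(res$numerical, ref[g$N + 1, i4])

  # a single-alpha sweep is just a direct solve
  sol <- solve_crisp(at_sample(cfg$model, 0, 1), g)
  expect_identical(res$numerical, solution_at(sol, 4, 0.05))
})

test_that("grid refinement shrinks the error and flags unstable pairs", {
  res <- grid_refinement()
  expect_true(all(res$stable))
  expect_false(any(res$blew_up))
  expect_true(all(diff(res$max_abs_error) < 0))

  # determinism: a repeated pair yields identical rows
  pair <- tibble::tibble(dx = c(0.5, 0.5), dt = c(0.0025, 0.0025))
  rep2 <- grid_refinement(step_pairs = pair)
  expect_identical(rep2[1, ], rep2[2, ])

  # an unstable pair is refused with the bound in the message...
  bad <- tibble::tibble(dx = 0.25, dt = 0.01)
  expect_error(grid_refinement(step_pairs = bad), "bound")
  # ...and runs under force_unstable with growth reported
  forced <- grid_refinement(step_pairs = bad, force_unstable = TRUE)
  expect_false(forced$stable)
  expect_true(forced$blew_up || forced$growth_factor > 1)
})

test_that("fixtures are deterministic and the registry is enforced", {
  f1 <- generate_fixture("worked_example", seed = 1)
  f2 <- generate_fixture("worked_example", seed = 999)
  expect_identical(f1$ic_table, f2$ic_table)  # seed-independent preset
  expect_identical(f1$preset$args, f2$preset$args)

  r1 <- generate_fixture("random_tri_ic", seed = 7)
  r2 <- generate_fixture("random_tri_ic", seed = 7)
  expect_identical(r1$ic_table, r2$ic_table)
  expect_identical(unclass(r1$preset$phi), unclass(r2$preset$phi))
  r3 <- generate_fixture("random_tri_ic", seed = 8)
  expect_false(identical(r1$ic_table$u0, r3$ic_table$u0))

  ch <- generate_fixture("classical_heat")
  expect_equal(ch$preset$grid$alpha, 1)
  expect_equal(ch$ic_table$u0, sin(pi * ch$ic_table$x))

  expect_error(generate_fixture("no_such_kind"), "registry")
})

test_that("configs round-trip through JSON and YAML and rebuild the preset", {
  cfg <- preset_worked_example(alpha = 0.8, dx = 0.4, L = 8.4)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, jpath)
  rebuilt <- build_config(read_config(jpath))
  expect_equal(rebuilt$args, cfg$args, tolerance = 0)
  expect_equal(rebuilt$grid$alpha, 0.8)

  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, ypath)
  expect_equal(build_config(read_config(ypath))$args, cfg$args, tolerance = 0)
})

test_that("every run can emit a manifest naming its outputs", {
  cfg <- preset_worked_example()
  path <- withr::local_tempfile(fileext = ".json")
  run_manifest(cfg, outputs = c("error_table.csv"), path = path,
               stability = stability_report(cfg$grid, 0.0025))
  man <- jsonlite::fromJSON(path)
  expect_equal(man$preset, "preset_worked_example")
  expect_equal(man$outputs, "error_table.csv")
  expect_true(man$stability$stable_prop1)
  expect_type(man$config_hash, "character")
})
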