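# Assembly and symbolic reduction.

test_that("bond variables are allocated deterministically per bond", {
  bg <- ab_model()
  bv <- bond_variables(bg)
  expect_equal(bv$effort, paste0("e_", seq_len(nrow(bv))))
  expect_equal(bv$flow, paste0("f_", seq_len(nrow(bv))))
  bv2 <- bond_variables(ab_model())  # identical construction run
  expect_identical(bv, bv2)
  expect_equal(nrow(bond_variables(bondgraph())), 0)
})

test_that("junction equations implement the two conservation laws", {
  eqs <- junction_equations("zero", c(1, 2, 3), c(1, 1, -1))
  txt <- vapply(eqs, function(r) paste(deparse1(r$lhs), "=", deparse1(r$rhs)),
                character(1))
  expect_setequal(txt, c("e_1 = e_2", "e_1 = e_3", "f_1 + f_2 - f_3 = 0"))
  eqs1 <- junction_equations("one", c(1, 2, 3), c(1, 1, -1))
  txt1 <- vapply(eqs1, function(r) paste(deparse1(r$lhs), "=", deparse1(r$rhs)),
                 character(1))
  expect_setequal(txt1, c("f_1 = f_2", "f_1 = f_3", "e_1 + e_2 - e_3 = 0"))
})

test_that("substituting junction constraints annihilates the signed power sum", {
  for (kind in c("zero", "one")) {
    eqs <- lapply(junction_equations(kind, 1:3, c(1, -1, 1)),
                  function(r) call("-", r$lhs, r$rhs))
    sol <- bondgraphr:::solve_linear_system(eqs, c(paste0("e_", 1:3), paste0("f_", 1:3)))
    pw <- quote(e_1 * f_1 - e_2 * f_2 + e_3 * f_3)
    expect_symbolic_zero(bondgraphr:::expr_subst(pw, sol$solutions))
  }
})

test_that("assembly counts equations and flags dangling ports", {
  bg <- bondgraph() |>
    add_node(component("Se", "src", es = 2)) |>
    add_node(component("C", "cap", C = 1, q = 0)) |>
    add_node(junction("one", "loop")) |>
    connect("src", "loop") |> connect("loop", "cap")
  raw <- assemble(bg)
  # 2 bonds -> 4 bond variables; Se (1) + C (2) + junction (2) equations
  expect_length(raw$bond_vars, 4)
  expect_length(raw$equations, 5)
  # dangling reverse port of an Re is reported by name
  bad <- bondgraph(globals = unit_globals()) |>
    add_node(component("Ce", "A", K = 1)) |>
    add_node(component("Re", "rx", kappa = 1)) |>
    connect("A", port("rx", 0))
  expect_error(assemble(bad), "port 1 of component 'rx'")
  # equation count does not depend on bond insertion order
  bg_r <- bondgraph() |>
    add_node(component("Se", "src", es = 2)) |>
    add_node(component("C", "cap", C = 1, q = 0)) |>
    add_node(junction("one", "loop")) |>
    connect("loop", "cap") |> connect("src", "loop")
  expect_length(assemble(bg_r)$equations, length(raw$equations))
})

test_that("source-resistor loop reduces to Ohm's law with no states", {
  bg <- bondgraph() |>
    add_node(component("Se", "src", es = 6)) |>
    add_node(component("R", "res", R = 2)) |>
    add_node(junction("one", "loop")) |>
    connect("src", "loop") |> connect("loop", "res")
  sys <- reduce_system(assemble(bg))
  expect_length(sys$states, 0)
  expect_true(sys$is_ode)
  # current through the loop: E/R = 3, visible as power E^2/R = 18 on bond 1
  expect_equal(eval(sys$observables$powers$P_1, list()), 18)
})

test_that("a transformer with ratio 1 is a structural no-op", {
  bg <- ab_model()
  sys0 <- reduce_system(assemble(bg))
  for (b in seq_along(bg$bonds)) {
    bg1 <- insert_node(bg, b, component("TF", "unit_tf", n = 1))
    sys1 <- reduce_system(assemble(bg1))
    expect_true(systems_equal(sys0, sys1))
  }
})

test_that("subsystem flattening matches hand-flattened models", {
  # three fixture cases: wrapped species+junction, wrapped reaction half,
  # and a two-level nest, each against its flat equivalent
  flat_ab <- function() reduce_system(assemble(ab_model()))

  # case 1: wrap (Ce:A -> 0-junction), expose the junction
  inner <- bondgraph(globals = unit_globals()) |>
    add_node(component("Ce", "A", K = 1, x = 1)) |>
    add_node(junction("zero", "JA")) |>
    connect("A", "JA")
  sub <- as_subsystem(inner, list(port("JA", 1)), "pool")
  outer <- bondgraph(globals = unit_globals()) |>
    add_node(sub) |>
    add_node(component("Re", "r1", kappa = 1)) |>
    add_node(junction("zero", "JB")) |>
    add_node(component("Ce", "B", K = 1, x = 0)) |>
    connect("pool", port("r1", 0)) |>
    connect(port("r1", 1), "JB") |>
    connect("JB", "B")
  sys <- reduce_system(assemble(outer))
  expect_true(systems_equal(flat_ab(), sys,
                            rename = c(`x_pool/A` = "x_A")))

  # case 2: wrap the reaction element itself
  rx_inner <- bondgraph(globals = unit_globals()) |>
    add_node(component("Re", "r1", kappa = 1))
  rx_sub <- as_subsystem(rx_inner, list(port("r1", 0), port("r1", 1)), "rx")
  outer2 <- bondgraph(globals = unit_globals()) |>
    add_node(component("Ce", "A", K = 1, x = 1)) |>
    add_node(junction("zero", "JA")) |>
    add_node(rx_sub) |>
    add_node(junction("zero", "JB")) |>
    add_node(component("Ce", "B", K = 1, x = 0)) |>
    connect("A", "JA") |> connect("JA", port("rx", 0)) |>
    connect(port("rx", 1), "JB") |> connect("JB", "B")
  sys2 <- reduce_system(assemble(outer2))
  expect_true(systems_equal(flat_ab(), sys2))

  # case 3: two-level nesting
  mid <- bondgraph(globals = unit_globals()) |> add_node(sub)
  sub2 <- as_subsystem(mid, list(port("pool", 0)), "outerpool")
  outer3 <- bondgraph(globals = unit_globals()) |>
    add_node(sub2) |>
    add_node(component("Re", "r1", kappa = 1)) |>
    add_node(junction("zero", "JB")) |>
    add_node(component("Ce", "B", K = 1, x = 0)) |>
    connect("outerpool", port("r1", 0)) |>
    connect(port("r1", 1), "JB") |>
    connect("JB", "B")
  sys3 <- reduce_system(assemble(outer3))
  expect_true(systems_equal(flat_ab(), sys3,
                            rename = c(`x_outerpool/pool/A` = "x_A")))
})

test_that("reduction flags DAEs and structural singularities", {
  # two effort sources with different values forced equal on a 0-junction
  bad <- bondgraph() |>
    add_node(component("Se", "s1", es = 1)) |>
    add_node(component("Se", "s2", es = 2)) |>
    add_node(junction("zero", "j")) |>
    connect("s1", "j") |> connect("s2", "j")
  expect_error(reduce_system(assemble(bad)), "structurally singular")
  # compatible sources are fine (constraint reduces to 0 = 0)
  ok <- bondgraph() |>
    add_node(component("Se", "s1", es = 2)) |>
    add_node(component("Se", "s2", es = 2)) |>
    add_node(junction("zero", "j")) |>
    connect("s1", "j") |> connect("s2", "j")
  expect_silent(reduce_system(assemble(ok)))
})

test_that("reduction is idempotent", {
  sys <- reduce_system(assemble(abc_cycle(globals = unit_globals())))
  again <- reduce_system(sys)
  expect_true(systems_equal(sys, again))
  expect_equal(names(again$states), names(sys$states))
})

test_that("chemostatted species never appear as states", {
  bg <- to_bondgraph(parse_reactions("A <--> B\nB <--> C"), chemostats = c("A", "C"),
                     globals = unit_globals())
  sys <- reduce_system(assemble(bg))
  expect_identical(names(sys$states), "x_B")
  expect_false(any(grepl("x_A|x_C", names(sys$states))))
  # but chemostats still drive the fluxes
  expect_true("xs_A" %in% all.vars(sys$observables$fluxes$r1))
})

test_that("equation text output is deterministic and parseable", {
  sys <- reduce_system(assemble(ab_model()))
  txt <- equations_text(sys)
  expect_equal(txt, c("d x_A/dt = -x_A + x_B", "d x_B/dt = x_A - x_B"))
  expect_identical(txt, equations_text(reduce_system(assemble(ab_model()))))
  lt <- equations_text(sys, format = "latex")
  expect_length(lt, 2)
  expect_true(all(grepl("\\\\frac\\{d", lt)))
  expect_error(equations_text(sys, format = "html"), "arg")
})

test_that("stored energy decays in closed dissipative systems", {
  sys <- reduce_system(assemble(abc_cycle(K = c(A = 2, B = 1, C = 0.5),
                                          x0 = c(A = 2, B = 0.3, C = 0.7),
                                          globals = unit_globals())))
  tr <- simulate_model(sys, c(0, 5), n_out = 101)
  expect_true(all(diff(tr$E_total) <= 1e-9))
})
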