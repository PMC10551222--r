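# Structural graph model and editing operations.

test_that("add_node adds vertices without bonds and rejects duplicates", {
  bg <- add_node(bondgraph(), component("C", "mem", C = 1))
  gv <- graph_view(bg)
  expect_equal(gv$n_vertices, 1)
  expect_equal(gv$n_bonds, 0)
  expect_error(add_node(bg, component("R", "mem")), "already exists")
  # the full ion pore fixture carries 11 vertices, added one by one
  expect_equal(graph_view(ion_pore())$n_vertices, 11)
})

test_that("connect resolves free ports, orients bonds, and enforces arity", {
  bg <- bondgraph() |>
    add_node(component("C", "mem", C = 1)) |>
    add_node(junction("zero", "j"))
  bg <- connect(bg, "mem", "j")
  gv <- graph_view(bg)
  expect_equal(gv$n_bonds, 1)
  expect_equal(gv$adjacency$from, "mem")
  expect_equal(gv$adjacency$to, "j")
  # one-port C is now saturated
  bg2 <- add_node(bg, junction("zero", "j2"))
  expect_error(connect(bg2, "mem", "j2"), "no free port")
  # junction-junction connections allocate ports on demand
  bg2 <- connect(bg2, "j", "j2")
  expect_equal(graph_view(bg2)$n_bonds, 2)
  expect_error(connect(bg2, port("j", 5), port("j", 5)), "port to itself")
})

test_that("disconnect frees both ports and rejects unknown bonds", {
  bg <- bondgraph() |>
    add_node(component("C", "mem", C = 1)) |>
    add_node(junction("zero", "j")) |>
    connect("mem", "j")
  bg2 <- disconnect(bg, 1)
  expect_equal(graph_view(bg2)$n_bonds, 0)
  bg3 <- connect(bg2, "mem", "j")  # ports free again
  expect_equal(graph_view(bg3)$n_bonds, 1)
  expect_error(disconnect(bg2, 1), "no such bond")
})

test_that("swap preserves adjacency and swap-back restores the graph", {
  bg <- bondgraph() |>
    add_node(component("C", "c1", C = 1)) |>
    add_node(junction("zero", "j")) |>
    connect("c1", "j")
  sw <- swap_node(bg, "c1", component("R", "r1", R = 2))
  expect_equal(graph_view(sw)$n_bonds, 1)
  expect_equal(sw$bonds[[1]]$src, "r1")
  back <- swap_node(sw, "r1", component("C", "c1", C = 1))
  expect_identical(graph_view(back)$neighbors, graph_view(bg)$neighbors)
  # arity mismatch: a 3-bond junction cannot become a one-port
  bg3 <- bondgraph() |>
    add_node(junction("zero", "hub")) |>
    add_node(component("C", "a", C = 1)) |>
    add_node(component("C", "b", C = 1)) |>
    add_node(component("C", "c", C = 1)) |>
    connect("a", "hub") |> connect("b", "hub") |> connect("c", "hub")
  expect_error(swap_node(bg3, "hub", component("C", "z", C = 1)), "port")
})

test_that("insert_node splits a bond and preserves orientation", {
  bg <- bondgraph() |>
    add_node(component("Se", "s", es = 1)) |>
    add_node(component("C", "c", C = 1)) |>
    connect("s", "c")
  bg2 <- insert_node(bg, 1, junction("zero", "mid"))
  gv <- graph_view(bg2)
  expect_equal(gv$n_vertices, graph_view(bg)$n_vertices + 1)
  expect_equal(gv$n_bonds, graph_view(bg)$n_bonds + 1)
  expect_equal(bg2$bonds[[1]]$src, "s")
  expect_equal(bg2$bonds[[1]]$dst, "mid")
  expect_equal(bg2$bonds[[2]]$src, "mid")
  expect_equal(bg2$bonds[[2]]$dst, "c")
  # a saturated one-port cannot be inserted into a bond
  expect_error(insert_node(bg2, 1, component("C", "c2", C = 1)),
               "junction or a two-port")
  # nor can a vertex that is already in the graph
  expect_error(insert_node(bg2, 1, junction("zero", "mid")), "already exists")
})

test_that("merge_nodes unifies same-object vertices and checks compatibility", {
  # two subgraphs each with their own copy of species A
  bg <- bondgraph(globals = unit_globals()) |>
    add_node(component("Ce", "A1", K = 1)) |>
    add_node(junction("zero", "jx")) |>
    add_node(component("Ce", "A2", K = 1)) |>
    add_node(junction("zero", "jy")) |>
    connect("A1", "jx") |> connect("A2", "jy")
  m <- merge_nodes(bg, "A1", "A2")
  gv <- graph_view(m)
  expect_equal(gv$n_vertices, 3)
  expect_equal(gv$n_bonds, 2)  # merge preserves total bond count
  expect_setequal(gv$neighbors$A1, c("jx", "jy"))
  # kind mismatch
  bg2 <- bondgraph() |>
    add_node(junction("zero", "z")) |>
    add_node(junction("one", "o"))
  expect_error(merge_nodes(bg2, "z", "o"), "different kinds")
  # merging junctions pools their bonds: 2 + 3 -> 5
  hub <- bondgraph()
  for (nm in letters[1:5]) hub <- add_node(hub, component("C", nm, C = 1))
  hub <- hub |>
    add_node(junction("zero", "p")) |> add_node(junction("zero", "q")) |>
    connect("a", "p") |> connect("b", "p") |>
    connect("c", "q") |> connect("d", "q") |> connect("e", "q")
  hub <- merge_nodes(hub, "p", "q")
  expect_length(graph_view(hub)$neighbors$p, 5)
  # conflicting parameter values refuse to merge
  bg3 <- bondgraph() |>
    add_node(component("C", "u", C = 1)) |>
    add_node(component("C", "v", C = 2))
  expect_error(merge_nodes(bg3, "u", "v"), "differs")
  # merged one-port stores carry all bonds and still assemble (implicit
  # 0-junction semantics: equal effort, flows summed)
  bg4 <- bondgraph(globals = unit_globals()) |>
    add_node(component("Ce", "u", K = 1, x = 1)) |>
    add_node(component("Ce", "v", K = 1, x = 1)) |>
    add_node(junction("zero", "ju")) |> add_node(junction("zero", "jv")) |>
    connect("u", "ju") |> connect("v", "jv")
  m4 <- merge_nodes(bg4, "u", "v")
  expect_length(graph_view(m4)$neighbors$u, 2)
  # two-port components cannot grow past their arity
  bg5 <- bondgraph(globals = unit_globals()) |>
    add_node(component("TF", "t1", n = 1)) |>
    add_node(component("TF", "t2", n = 1)) |>
    add_node(junction("zero", "j1")) |> add_node(junction("zero", "j2")) |>
    add_node(junction("zero", "j3")) |> add_node(junction("zero", "j4")) |>
    connect("j1", port("t1", 0)) |> connect(port("t1", 1), "j2") |>
    connect("j3", port("t2", 0)) |> connect(port("t2", 1), "j4")
  expect_error(merge_nodes(bg5, "t1", "t2"), "port")
  # merging shared species across two reaction subgraphs reproduces the
  # directly built chain A = B = C
  half <- function(sA, sB, rname) {
    bondgraph(globals = unit_globals()) |>
      add_node(component("Ce", sA, K = 1, x = 1)) |>
      add_node(component("Ce", sB, K = 1, x = 1)) |>
      add_node(component("Re", rname, kappa = 1)) |>
      connect(sA, port(rname, 0)) |> connect(port(rname, 1), sB)
  }
  g1 <- half("A", "B", "r1")
  g2 <- half("Bdup", "C", "r2")
  joint <- bondgraph(globals = unit_globals())
  for (v in c(g1$vertices, g2$vertices)) joint <- add_node(joint, v)
  for (b in c(g1$bonds, g2$bonds)) {
    joint <- connect(joint, port(b$src, b$src_port), port(b$dst, b$dst_port))
  }
  joint <- swap_node(joint, "Bdup", component("Ce", "Bd", K = 1, x = 1))
  joint <- merge_nodes(joint, "B", "Bd")
  chain <- to_bondgraph(parse_reactions(c("A <--> B", "B <--> C")),
                        K = c(A = 1, B = 1, C = 1), kappa = c(r1 = 1, r2 = 1),
                        x0 = c(A = 1, B = 1, C = 1), globals = unit_globals())
  expect_true(systems_equal(reduce_system(assemble(chain)),
                            reduce_system(assemble(joint))))
})

test_that("graph_view reports a symmetric undirected adjacency", {
  bg <- bondgraph() |>
    add_node(component("Se", "A", es = 1)) |>
    add_node(junction("one", "J")) |>
    add_node(component("C", "B", C = 1)) |>
    connect("A", "J") |> connect("J", "B")
  gv <- graph_view(bg)
  expect_setequal(gv$neighbors$J, c("A", "B"))
  expect_identical(gv$adjacency_matrix, t(gv$adjacency_matrix))
  empty <- graph_view(bondgraph())
  expect_equal(empty$n_vertices, 0)
  expect_equal(empty$n_bonds, 0)
  expect_length(empty$neighbors, 0)
  expect_equal(nrow(empty$adjacency), 0)
})

test_that("random edit sequences preserve bond/port integrity", {
  set.seed(42)
  for (rep in seq_len(40)) {
    bg <- bondgraph(globals = unit_globals())
    n_c <- sample(2:4, 1)
    for (i in seq_len(n_c)) bg <- add_node(bg, component("Ce", paste0("S", i), K = 1))
    for (i in seq_len(n_c)) bg <- add_node(bg, junction("zero", paste0("J", i)))
    for (i in seq_len(n_c)) bg <- connect(bg, paste0("S", i), paste0("J", i))
    for (step in seq_len(sample(3:8, 1))) {
      op <- sample(c("connect", "disconnect", "insert", "swap"), 1)
      ok <- try(switch(op,
        connect = {
          js <- sample(paste0("J", seq_len(n_c)), 2)
          bg <- connect(bg, js[1], js[2])
        },
        disconnect = if (length(bg$bonds)) {
          bg <- disconnect(bg, sample(length(bg$bonds), 1))
        },
        insert = if (length(bg$bonds)) {
          bg <- insert_node(bg, sample(length(bg$bonds), 1),
                            junction("zero", paste0("ins", step, "_", rep)))
        },
        swap = {
          j <- sample(paste0("J", seq_len(n_c)), 1)
          bg <- swap_node(bg, j, junction("zero", paste0("sw", step, "_", rep)))
          # keep handle names stable by swapping straight back
          bg <- swap_node(bg, paste0("sw", step, "_", rep), junction("zero", j))
        }), silent = TRUE)
      expect_true(bondgraphr:::.check_graph_invariants(bg))
    }
  }
})

test_that("subsystems wrap, nest, and expose ports correctly", {
  inner <- bondgraph(globals = unit_globals()) |>
    add_node(component("Ce", "A", K = 1, x = 1)) |>
    add_node(junction("zero", "j")) |>
    connect("A", "j")
  expect_error(as_subsystem(inner, list(), "sub"), "at least one")
  expect_error(as_subsystem(inner, list(port("A", 0)), "sub"), "already bound")
  sub <- as_subsystem(inner, list(port("j", 1)), "sub")
  outer <- bondgraph(globals = unit_globals()) |>
    add_node(sub) |>
    add_node(component("C", "c", C = 1)) |>
    connect("sub", "c")
  flat <- flatten_bg(outer)
  expect_setequal(names(flat$vertices), c("sub/A", "sub/j", "c"))
  expect_equal(length(flat$bonds), 2)
  # two-level nesting flattens recursively
  mid <- bondgraph(globals = unit_globals()) |>
    add_node(sub)
  sub2 <- as_subsystem(mid, list(port("sub", 0)), "outer")
  top <- bondgraph(globals = unit_globals()) |>
    add_node(sub2) |>
    add_node(component("C", "c", C = 1)) |>
    connect("outer", "c")
  flat2 <- flatten_bg(top)
  expect_true("outer/sub/A" %in% names(flat2$vertices))
  expect_equal(length(flat2$bonds), 2)
})

test_that("disconnecting inside a wrapped inner graph leaves the outer intact", {
  inner <- bondgraph(globals = unit_globals()) |>
    add_node(component("Ce", "A", K = 1)) |>
    add_node(junction("zero", "j")) |>
    connect("A", "j")
  sub <- as_subsystem(inner, list(port("j", 1)), "sub")
  outer <- bondgraph(globals = unit_globals()) |>
    add_node(sub) |>
    add_node(component("C", "c", C = 1)) |>
    connect("sub", "c")
  inner2 <- disconnect(inner, 1)  # value semantics: the subsystem keeps its copy
  expect_equal(graph_view(inner2)$n_bonds, 0)
  expect_equal(length(flatten_bg(outer)$bonds), 2)
})
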