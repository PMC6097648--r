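test_that("normality testing behaves across sample classes", {
    expect_error(testNormality(c(1, 2)), "at least 3")
    expect_warning(p <- testNormality(rep(5, 10)), "constant")
    expect_true(is.na(p))

    set.seed(50)
    normalOk <- sum(vapply(1:100, function(i)
        testNormality(rnorm(50)) > 0.05, logical(1)))
    expect_gte(normalOk, 90)

    set.seed(51)
    expoCaught <- sum(vapply(1:100, function(i)
        testNormality(rexp(50)) <= 0.05, logical(1)))
    expect_gte(expoCaught, 90)
})

test_that("star codes follow the published thresholds inclusively", {
    expect_equal(stars(c(0.2, 0.06)), c("ns", "ns"))
    expect_equal(stars(0.04), "*")
    expect_equal(stars(0.05), "*")       # boundary inclusive
    expect_equal(stars(0.01), "**")
    expect_equal(stars(0.001), "***")    # boundary inclusive
    expect_equal(stars(0.0005), "***")
    expect_error(stars(1.2), "\\[0, 1\\]")
    expect_error(stars(-0.1), "\\[0, 1\\]")
})

test_that("equal group means give a null ANOVA", {
    tab <- data.frame(specimen_id = as.character(1:6),
                      group = rep(c("a", "b"), each = 3),
                      measure = "m", value = c(1, 2, 3, 3, 1, 2))
    rep <- anovaTukey(tab, "m")
    expect_equal(rep@anova$F, 0)
    expect_equal(rep@anova$p, 1)
    expect_equal(rep@tukey$stars, "ns")
})

test_that("two-group ANOVA squares the pooled t statistic", {
    set.seed(52)
    tab <- data.frame(specimen_id = as.character(1:14),
                      group = rep(c("a", "b"), c(6, 8)),
                      measure = "m",
                      value = c(rnorm(6, 10), rnorm(8, 12)))
    rep <- anovaTukey(tab, "m")
    tt <- t.test(value ~ group, data = tab, var.equal = TRUE)
    expect_equal(rep@anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(rep@anova$p, tt$p.value, tolerance = 1e-10)
})

test_that("a three-group dataset matches hand-computed F and Tukey p", {
    ## classic balanced example, oracle computed from first principles
    vals <- list(a = c(18, 20, 21, 23), b = c(22, 25, 27, 26),
                 c = c(28, 30, 31, 29))
    tab <- data.frame(specimen_id = as.character(1:12),
                      group = rep(names(vals), each = 4),
                      measure = "m", value = unlist(vals))
    rep <- anovaTukey(tab, "m")

    k <- 3; n <- 4; N <- 12
    gm <- mean(unlist(vals))
    ssb <- n * sum((vapply(vals, mean, numeric(1)) - gm)^2)
    ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
    Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
    expect_equal(rep@anova$F, Fstat, tolerance = 1e-6)
    expect_equal(rep@anova$p, pf(Fstat, k - 1, N - k, lower.tail = FALSE),
                 tolerance = 1e-6)

    ## Tukey p for the b-a pair via the studentized range directly
    mse <- ssw / (N - k)
    qObs <- abs(mean(vals$b) - mean(vals$a)) / sqrt(mse / n)
    pBA <- ptukey(qObs, k, N - k, lower.tail = FALSE)
    got <- rep@tukey$p[rep@tukey$comparison == "b-a"]
    expect_equal(got, pBA, tolerance = 1e-6)

    ## means and SEM follow the animals-per-group convention
    expect_equal(rep@groupMeans$mean, vapply(vals, mean, numeric(1)),
                 ignore_attr = TRUE)
    expect_equal(rep@groupMeans$sem,
                 vapply(vals, function(v) sd(v) / 2, numeric(1)),
                 ignore_attr = TRUE)
})

test_that("undersized groups are rejected by name", {
    tab <- data.frame(specimen_id = as.character(1:5),
                      group = c("a", "a", "a", "a", "tiny"),
                      measure = "m", value = 1:5)
    expect_error(anovaTukey(tab, "m"), "tiny")
})

test_that("Tukey HSD controls family-wise error under the null", {
    set.seed(53)
    reps <- 500
    anyStar <- vapply(seq_len(reps), function(i) {
        tab <- data.frame(specimen_id = as.character(1:15),
                          group = rep(c("a", "b", "c"), each = 5),
                          measure = "m", value = rnorm(15))
        any(anovaTukey(tab, "m")@tukey$p <= 0.05)
    }, logical(1))
    rate <- mean(anyStar)
    expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))  # MC tolerance
})

test_that("label permutations leave the F distribution unchanged", {
    set.seed(54)
    values <- rnorm(18)
    groups <- rep(c("a", "b", "c"), each = 6)
    Fof <- function(g) {
        tab <- data.frame(specimen_id = as.character(1:18), group = g,
                          measure = "m", value = values)
        anovaTukey(tab, "m")@anova$F
    }
    perms <- replicate(300, Fof(sample(groups)))
    ## exchangeable data: permutation F follows the reference F(2, 15)
    ks <- suppressWarnings(ks.test(perms, function(q) pf(q, 2, 15)))
    expect_gt(ks$p.value, 0.005)
    ## and the observed labelling is nothing special
    expect_gt(mean(perms >= Fof(groups)), 0.01)
})

test_that("long group tables are built from results frames", {
    res <- data.frame(specimenId = c("s1", "s2"), group = c("g1", "g2"),
                      m1 = c(1, 2), m2 = c(3, 4))
    tab <- groupTable(res)
    expect_setequal(unique(tab$measure), c("m1", "m2"))
    expect_equal(nrow(tab), 4)
    expect_error(groupTable(data.frame(x = 1)), "group")
})
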