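Package: socioblocks
Title: Mixed-Membership Block Models of Cognitive Profiles and Multilayer Classroom Sociograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers children's cognitive profiles from bipartite student-by-task
    quintile scores with a mixed-membership stochastic block model fitted by
    variational expectation-maximization, and relates those profiles to
    multilayer peer-nomination sociograms (work, play and friendship layers)
    through edge-overlap, cognitive-distance assortativity and PageRank status
    statistics, each with its permutation or degree-preserving rewiring null
    model. Includes a planted-truth synthetic data generator for classrooms
    and nomination networks, holdout prediction experiments, and a
    nonparametric hypothesis-testing toolkit (Mann-Whitney U, Spearman,
    Shapiro-Wilk gatekeeping, Hodges-Lehmann effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
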