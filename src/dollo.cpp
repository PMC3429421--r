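#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dollo parsimony scoring of binary presence/absence characters on a rooted
// tree. States: 0 = absent, 1 = present, 2 = unknown. A character may be
// gained at most once (on any edge, including the root's stem) and lost any
// number of times; the state ancestral to the root is absent. Unknown leaves
// take whichever state minimises the step count.
//
// Dynamic programme over nodes, three costs per node v:
//   a0[v] : v absent, no gain anywhere in v's subtree
//   a1[v] : v absent, exactly one gain somewhere below v
//   pr[v] : v present (the gain lies on or above v's stem)
// Steps for the column = min(a0[root], a1[root], 1 + pr[root]).

static const double INF = 1e18;

struct Tree {
    int root;
    std::vector<int> order;                 // postorder over reachable nodes
    std::vector<std::vector<int> > kids;
};

static Tree build_tree(const IntegerVector& parent, int root)
{
    int m = parent.size();
    Tree t;
    t.root = root - 1;
    t.kids.assign(m, std::vector<int>());
    for (int i = 0; i < m; i++) {
        int p = parent[i];
        if (p > 0) t.kids[p - 1].push_back(i);
    }
    // iterative DFS: reverse preorder -> postorder
    std::vector<int> stack, pre;
    stack.push_back(t.root);
    while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        pre.push_back(v);
        for (size_t k = 0; k < t.kids[v].size(); k++)
            stack.push_back(t.kids[v][k]);
    }
    t.order.assign(pre.rbegin(), pre.rend());
    return t;
}

static double score_column(const Tree& t, const std::vector<int>& state,
                           int n_tip, std::vector<double>& a0,
                           std::vector<double>& a1, std::vector<double>& pr)
{
    for (size_t oi = 0; oi < t.order.size(); oi++) {
        int v = t.order[oi];
        if (v < n_tip && t.kids[v].empty()) {
            int s = state[v];
            a0[v] = (s == 1) ? INF : 0.0;
            pr[v] = (s == 0) ? INF : 0.0;
            a1[v] = INF;
        } else {
            double sum0 = 0.0, sumP = 0.0, best1 = INF;
            const std::vector<int>& ch = t.kids[v];
            for (size_t k = 0; k < ch.size(); k++) {
                int c = ch[k];
                sum0 += a0[c];
                sumP += std::min(pr[c], 1.0 + a0[c]);
            }
            for (size_t k = 0; k < ch.size(); k++) {
                int c = ch[k];
                double gainhere = std::min(a1[c], 1.0 + pr[c]);
                double cand = sum0 - a0[c] + gainhere;
                if (cand < best1) best1 = cand;
            }
            a0[v] = std::min(sum0, INF);
            a1[v] = std::min(best1, INF);
            pr[v] = std::min(sumP, INF);
        }
    }
    double s = std::min(a0[t.root],
                        std::min(a1[t.root], 1.0 + pr[t.root]));
    return s;
}

// [[Rcpp::export]]
IntegerVector dollo_steps_cpp(IntegerVector parent, int root, int n_tip,
                              IntegerMatrix states)
{
    Tree t = build_tree(parent, root);
    int m = parent.size(), L = states.ncol();
    std::vector<double> a0(m), a1(m), pr(m);
    std::vector<int> col(m, 0);
    IntegerVector out(L);
    for (int j = 0; j < L; j++) {
        for (int i = 0; i < n_tip && i < m; i++) col[i] = states(i, j);
        out[j] = (int) score_column(t, col, n_tip, a0, a1, pr);
    }
    return out;
}

// Weighted total tree length; hot path of the heuristic search/bootstrap.
// [[Rcpp::export]]
double dollo_total_cpp(IntegerVector parent, int root, int n_tip,
                       IntegerMatrix states, NumericVector weights)
{
    Tree t = build_tree(parent, root);
    int m = parent.size(), L = states.ncol();
    std::vector<double> a0(m), a1(m), pr(m);
    std::vector<int> col(m, 0);
    double total = 0.0;
    for (int j = 0; j < L; j++) {
        if (weights[j] == 0.0) continue;
        for (int i = 0; i < n_tip && i < m; i++) col[i] = states(i, j);
        total += weights[j] * score_column(t, col, n_tip, a0, a1, pr);
    }
    return total;
}
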