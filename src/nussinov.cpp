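#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Watson-Crick plus G:U wobble pairing over the RNA/DNA alphabet (T == U)
static inline bool can_pair(char a, char b) {
    if (a == 'T') a = 'U';
    if (b == 'T') b = 'U';
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing (Nussinov) with a minimum hairpin loop of
// `min_loop` unpaired bases between any pair. Returns the pair count and
// one optimal pairing (1-based partner index, 0 = unpaired).
// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop = 3) {
    int n = seq.size();
    IntegerVector partner(n, 0);
    if (n == 0)
        return List::create(_["score"] = 0, _["partner"] = partner);
    std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = M[i + 1][j]; // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                if (!can_pair(seq[i], seq[k])) continue;
                int v = 1 + (k > i + 1 ? M[i + 1][k - 1] : 0) +
                        (k < j ? M[k + 1][j] : 0);
                if (v > best) best = v;
            }
            M[i][j] = best;
        }
    }
    // iterative traceback over subproblem intervals
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i < min_loop + 1) continue;
        if (M[i][j] == M[i + 1][j]) {
            stack.push_back(std::make_pair(i + 1, j));
            continue;
        }
        for (int k = i + min_loop + 1; k <= j; ++k) {
            if (!can_pair(seq[i], seq[k])) continue;
            int v = 1 + (k > i + 1 ? M[i + 1][k - 1] : 0) +
                    (k < j ? M[k + 1][j] : 0);
            if (v == M[i][j]) {
                partner[i] = k + 1;
                partner[k] = i + 1;
                if (k > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
                if (k < j) stack.push_back(std::make_pair(k + 1, j));
                break;
            }
        }
    }
    return List::create(_["score"] = M[0][n - 1], _["partner"] = partner);
}
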