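#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Disjoint-set find with path halving.
static int df_find(std::vector<int> &parent, int x) {
    while (parent[x] != x) {
        parent[x] = parent[parent[x]];
        x = parent[x];
    }
    return x;
}

static void df_union(std::vector<int> &parent, std::vector<int> &rank_,
                     int a, int b) {
    a = df_find(parent, a);
    b = df_find(parent, b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) rank_[a]++;
}

// Cluster sizes (descending) of the lattice under the current bond arrays.
// Node (x, y) has index x + y*L; the node owns the horizontal bond to
// (x+1 mod L, y) and the vertical bond to (x, y+1 mod L).
static IntegerVector lattice_census(int L, const std::vector<uint8_t> &h,
                                    const std::vector<uint8_t> &v) {
    const int n = L * L;
    std::vector<int> parent(n), rank_(n, 0);
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int y = 0; y < L; ++y) {
        for (int x = 0; x < L; ++x) {
            int id = x + y * L;
            if (h[id]) df_union(parent, rank_, id, ((x + 1) % L) + y * L);
            if (v[id]) df_union(parent, rank_, id, x + ((y + 1) % L) * L);
        }
    }
    std::vector<int> count(n, 0);
    for (int i = 0; i < n; ++i) count[df_find(parent, i)]++;
    std::vector<int> sizes;
    sizes.reserve(n);
    for (int i = 0; i < n; ++i)
        if (count[i] > 0) sizes.push_back(count[i]);
    std::sort(sizes.begin(), sizes.end(), std::greater<int>());
    return IntegerVector(sizes.begin(), sizes.end());
}

// [[Rcpp::export(name = ".se_simulate_cpp")]]
List se_simulate_cpp(int L, double p1, double p2, int burn_in_sweeps,
                     int n_samples, int stride_sweeps, double seed,
                     bool return_configs = false) {
    const int n = L * L;
    std::vector<uint8_t> h(n, 0), v(n, 0); // all bonds absent initially
    std::mt19937_64 rng(static_cast<uint64_t>(seed));
    std::uniform_int_distribution<int> pick(0, n - 1);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    List censuses(n_samples);
    List configs(return_configs ? n_samples : 0);
    NumericVector h_frac(n_samples), v_frac(n_samples);

    auto sweep = [&]() {
        for (int k = 0; k < n; ++k) {
            int id = pick(rng);
            int x = id % L, y = id / L;
            uint8_t hb = unif(rng) < p1 ? 1 : 0;
            uint8_t vb = unif(rng) < p2 ? 1 : 0;
            // both horizontal bonds incident to the node follow one draw
            h[id] = hb;
            h[((x - 1 + L) % L) + y * L] = hb;
            v[id] = vb;
            (void)x;
        }
    };

    for (int s = 0; s < burn_in_sweeps; ++s) sweep();
    for (int i = 0; i < n_samples; ++i) {
        int todo = (i == 0) ? 0 : stride_sweeps;
        for (int s = 0; s < todo; ++s) sweep();
        censuses[i] = lattice_census(L, h, v);
        int hc = 0, vc = 0;
        for (int k = 0; k < n; ++k) { hc += h[k]; vc += v[k]; }
        h_frac[i] = static_cast<double>(hc) / n;
        v_frac[i] = static_cast<double>(vc) / n;
        if (return_configs) {
            LogicalMatrix hm(L, L), vm(L, L);
            for (int y = 0; y < L; ++y)
                for (int x = 0; x < L; ++x) {
                    hm(x, y) = h[x + y * L] != 0;
                    vm(x, y) = v[x + y * L] != 0;
                }
            configs[i] = List::create(_["h"] = hm, _["v"] = vm);
        }
    }
    List out = List::create(_["censuses"] = censuses, _["h_frac"] = h_frac,
                            _["v_frac"] = v_frac);
    if (return_configs) out["configs"] = configs;
    return out;
}
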