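#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <functional>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Agent-based fission-fusion simulator. Ne indivisible edge-units, each with
// two endpoints; endpoints live in junction nodes of degree 1-3. Continuous
// time Gillespie over four channels:
//   tip-tip fusion    rate a1 * (admissible k=1 pairs)
//   tip-tip fission   rate b1 * X2
//   tip-side fusion   rate a2 * X1 * X2
//   tip-side fission  rate b2 * X3
// The two tips of one isolated unit are not an admissible fusion pair (no
// single-unit self loop); tips sharing a multi-unit cluster are admissible
// (rings form).

struct ABSim {
    int Ne;
    // endpoint e of unit u: e = 2u or 2u+1; node_of[e] = node id
    std::vector<int> node_of;
    // node -> up to 3 endpoint ids; degree 0 means free slot
    std::vector<std::array<int, 3>> ends;
    std::vector<int> degree;
    std::vector<int> free_nodes;
    // membership lists by degree (1,2,3) with per-node positions
    std::vector<int> bydeg[4];
    std::vector<int> pos;
    long long n_iso; // isolated units (both endpoints degree-1)
    std::mt19937_64 rng;
    std::uniform_real_distribution<double> unif{0.0, 1.0};

    ABSim(int Ne_, uint64_t seed) : Ne(Ne_), rng(seed) {
        node_of.resize(2 * Ne);
        ends.resize(2 * Ne);
        degree.assign(2 * Ne, 0);
        pos.assign(2 * Ne, -1);
        for (int e = 0; e < 2 * Ne; ++e) {
            node_of[e] = e;
            ends[e][0] = e;
            degree[e] = 1;
        }
        for (int nd = 0; nd < 2 * Ne; ++nd) list_add(nd, 1);
        n_iso = Ne;
    }

    void list_add(int nd, int k) {
        pos[nd] = bydeg[k].size();
        bydeg[k].push_back(nd);
    }
    void list_remove(int nd, int k) {
        int p = pos[nd];
        int last = bydeg[k].back();
        bydeg[k][p] = last;
        pos[last] = p;
        bydeg[k].pop_back();
        pos[nd] = -1;
    }
    void set_degree(int nd, int knew) {
        int kold = degree[nd];
        if (kold >= 1) list_remove(nd, kold);
        degree[nd] = knew;
        if (knew >= 1) list_add(nd, knew);
    }
    int unit_of(int e) const { return e / 2; }
    int mate(int e) const { return e ^ 1; }
    bool unit_isolated(int u) const {
        return degree[node_of[2 * u]] == 1 && degree[node_of[2 * u + 1]] == 1;
    }
    int rand_node(int k) {
        std::uniform_int_distribution<size_t> d(0, bydeg[k].size() - 1);
        return bydeg[k][d(rng)];
    }

    long long X(int k) const { return (long long)bydeg[k].size(); }

    // propensities
    double prop_ttfus(double a1) const {
        double x1 = (double)X(1);
        double pairs = x1 * (x1 - 1.0) / 2.0 - (double)n_iso;
        return pairs > 0 ? a1 * pairs : 0.0;
    }
    double prop_ttfis(double b1) const { return b1 * (double)X(2); }
    double prop_tsfus(double a2) const {
        return a2 * (double)X(1) * (double)X(2);
    }
    double prop_tsfis(double b2) const { return b2 * (double)X(3); }

    // isolation bookkeeping: call with the units whose endpoints a move
    // touches, before and after the structural change
    template <typename F>
    void with_iso(std::initializer_list<int> units, F&& change) {
        // dedupe (at most 3 units involved)
        int us[3]; int nu = 0;
        for (int u : units) {
            bool seen = false;
            for (int i = 0; i < nu; ++i) if (us[i] == u) seen = true;
            if (!seen) us[nu++] = u;
        }
        for (int i = 0; i < nu; ++i) if (unit_isolated(us[i])) n_iso--;
        change();
        for (int i = 0; i < nu; ++i) if (unit_isolated(us[i])) n_iso++;
    }

    // merge endpoint set of node b into node a
    void merge_nodes(int a, int b) {
        int ka = degree[a], kb = degree[b];
        for (int i = 0; i < kb; ++i) {
            int e = ends[b][i];
            ends[a][ka + i] = e;
            node_of[e] = a;
        }
        set_degree(a, ka + kb);
        set_degree(b, 0);
        free_nodes.push_back(b);
    }

    int new_node() {
        int nd = free_nodes.back();
        free_nodes.pop_back();
        return nd;
    }

    void tip_tip_fusion() {
        int n1, n2;
        do {
            n1 = rand_node(1);
            n2 = rand_node(1);
        } while (n1 == n2 ||
                 (unit_of(ends[n1][0]) == unit_of(ends[n2][0])));
        with_iso({unit_of(ends[n1][0]), unit_of(ends[n2][0])},
                 [&]() { merge_nodes(n1, n2); });
    }

    void tip_tip_fission() {
        int nd = rand_node(2);
        int e0 = ends[nd][0], e1 = ends[nd][1];
        with_iso({unit_of(e0), unit_of(e1)}, [&]() {
            int nb = new_node();
            ends[nd][0] = e0;
            set_degree(nd, 1);
            ends[nb][0] = e1;
            node_of[e1] = nb;
            set_degree(nb, 1);
        });
    }

    void tip_side_fusion() {
        int n1 = rand_node(1);
        int n2 = rand_node(2);
        with_iso({unit_of(ends[n1][0]), unit_of(ends[n2][0]),
                  unit_of(ends[n2][1])},
                 [&]() { merge_nodes(n2, n1); });
    }

    void tip_side_fission() {
        int nd = rand_node(3);
        std::uniform_int_distribution<int> d(0, 2);
        int i = d(rng);
        int e = ends[nd][i];
        with_iso({unit_of(ends[nd][0]), unit_of(ends[nd][1]),
                  unit_of(ends[nd][2])},
                 [&]() {
                     ends[nd][i] = ends[nd][2];
                     set_degree(nd, 2);
                     int nb = new_node();
                     ends[nb][0] = e;
                     node_of[e] = nb;
                     set_degree(nb, 1);
                 });
    }

    // returns dt, or -1 if absorbing
    double step(double a1, double b1, double a2, double b2) {
        double r1 = prop_ttfus(a1), r2 = prop_ttfis(b1);
        double r3 = prop_tsfus(a2), r4 = prop_tsfis(b2);
        double tot = r1 + r2 + r3 + r4;
        if (tot <= 0.0) return -1.0;
        double dt = -std::log(1.0 - unif(rng)) / tot;
        double r = unif(rng) * tot;
        if (r < r1) tip_tip_fusion();
        else if (r < r1 + r2) tip_tip_fission();
        else if (r < r1 + r2 + r3) tip_side_fusion();
        else tip_side_fission();
        return dt;
    }

    // cluster census over units connected through shared nodes
    IntegerVector census() const {
        std::vector<int> parent(Ne), rank_(Ne, 0);
        for (int u = 0; u < Ne; ++u) parent[u] = u;
        std::function<int(int)> find = [&](int x) {
            while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
            return x;
        };
        auto unite = [&](int a, int b) {
            a = find(a); b = find(b);
            if (a == b) return;
            if (rank_[a] < rank_[b]) std::swap(a, b);
            parent[b] = a;
            if (rank_[a] == rank_[b]) rank_[a]++;
        };
        for (int nd = 0; nd < 2 * Ne; ++nd) {
            int k = degree[nd];
            for (int i = 1; i < k; ++i)
                unite(unit_of(ends[nd][0]), unit_of(ends[nd][i]));
        }
        std::vector<int> count(Ne, 0);
        for (int u = 0; u < Ne; ++u) count[find(u)]++;
        std::vector<int> sizes;
        for (int u = 0; u < Ne; ++u)
            if (count[u] > 0) sizes.push_back(count[u]);
        std::sort(sizes.begin(), sizes.end(), std::greater<int>());
        return IntegerVector(sizes.begin(), sizes.end());
    }
};

// [[Rcpp::export(name = ".ab_simulate_cpp")]]
List ab_simulate_cpp(int Ne, double a1, double b1, double a2, double b2,
                     double burn_in, int n_samples, double stride,
                     double seed) {
    ABSim sim(Ne, static_cast<uint64_t>(seed));
    double t = 0.0;
    bool absorbed = false;
    List censuses(n_samples);
    IntegerMatrix Xk(n_samples, 3);

    auto advance = [&](double n_events) {
        for (double k = 0; k < n_events && !absorbed; ++k) {
            double dt = sim.step(a1, b1, a2, b2);
            if (dt < 0) { absorbed = true; break; }
            t += dt;
        }
    };

    advance(burn_in);
    for (int i = 0; i < n_samples; ++i) {
        if (i > 0) advance(stride);
        censuses[i] = sim.census();
        Xk(i, 0) = (int)sim.X(1);
        Xk(i, 1) = (int)sim.X(2);
        Xk(i, 2) = (int)sim.X(3);
        if ((long long)Xk(i, 0) + 2LL * Xk(i, 1) + 3LL * Xk(i, 2) !=
            2LL * Ne)
            stop("internal error: endpoint conservation violated");
    }
    // final unit graph (endpoint node ids) for external structural checks;
    // coincides with the state of the last census
    IntegerMatrix units(Ne, 2);
    for (int u = 0; u < Ne; ++u) {
        units(u, 0) = sim.node_of[2 * u] + 1;
        units(u, 1) = sim.node_of[2 * u + 1] + 1;
    }
    return List::create(_["censuses"] = censuses, _["Xk"] = Xk,
                        _["time"] = t, _["units"] = units,
                        _["absorbed"] = absorbed);
}
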