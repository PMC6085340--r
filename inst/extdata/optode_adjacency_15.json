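[[1,2],[1,9],[2,3],[2,9],[2,10],[3,4],[3,10],[3,11],[4,5],[4,11],[4,12],[5,6],[5,12],[5,13],[6,7],[6,13],[6,14],[7,8],[7,14],[7,15],[8,15],[9,10],[10,11],[11,12],[12,13],[13,14],[14,15]]
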