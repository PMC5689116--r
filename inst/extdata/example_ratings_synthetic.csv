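"item_id","reference","rater_id","rating"
"item1","present","rater1","present"
"item2","absent","rater1","absent"
"item3","present","rater1","present"
"item4","absent","rater1","absent"
"item5","absent","rater1","present"
"item6","present","rater1","present"
"item1","present","rater2","present"
"item2","absent","rater2","absent"
"item3","present","rater2","present"
"item4","absent","rater2","absent"
"item5","absent","rater2","absent"
"item6","present","rater2","present"
"item1","present","rater3","absent"
"item2","absent","rater3","present"
"item3","present","rater3","present"
"item4","absent","rater3","absent"
"item5","absent","rater3","absent"
"item6","present","rater3","present"
"item1","present","rater4","present"
"item2","absent","rater4","absent"
"item3","present","rater4","present"
"item4","absent","rater4","absent"
"item5","absent","rater4","absent"
"item6","present","rater4","present"
"item1","present","rater5","present"
"item2","absent","rater5","absent"
"item3","present","rater5","present"
"item4","absent","rater5","absent"
"item5","absent","rater5","absent"
"item6","present","rater5","present"
"item1","present","rater6","present"
"item2","absent","rater6","present"
"item3","present","rater6","present"
"item4","absent","rater6","absent"
"item5","absent","rater6","absent"
"item6","present","rater6","absent"
"item1","present","rater7","present"
"item2","absent","rater7","absent"
"item3","present","rater7","present"
"item4","absent","rater7","absent"
"item5","absent","rater7","absent"
"item6","present","rater7","present"
"item1","present","rater8","present"
"item2","absent","rater8","absent"
"item3","present","rater8","present"
"item4","absent","rater8","absent"
"item5","absent","rater8","absent"
"item6","present","rater8","present"
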